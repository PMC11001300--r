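#' Read gene models from a GFF3 file
#'
#' Consumes `gene` features only. GFF3 coordinates are 1-based inclusive;
#' they are converted to the package's internal 0-based half-open
#' convention (`start - 1`, `end`). Malformed records (end < start,
#' unknown strand, non-numeric coordinates) are skipped with a warning
#' naming the offending line number.
#'
#' @param path GFF3 file path (or a character vector of GFF3 lines).
#' @return Tibble with columns `gene_id`, `seq_id`, `start`, `end`
#'   (0-based half-open), `strand`, sorted by (seq_id, start).
#' @export
read_gene_models <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  empty <- tibble(gene_id = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character())
  if (length(idx) == 0L) return(empty)
  rows <- purrr::map(idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      warn(sprintf("GFF line %d: fewer than 9 columns; skipped", i))
      return(NULL)
    }
    if (f[3] != "gene") return(NULL)
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || end < start) {
      warn(sprintf("GFF line %d: bad coordinates (%s, %s); skipped",
                   i, f[4], f[5]))
      return(NULL)
    }
    if (!f[7] %in% c("+", "-")) {
      warn(sprintf("GFF line %d: unknown strand '%s'; skipped", i, f[7]))
      return(NULL)
    }
    id <- sub(".*ID=([^;]+).*", "\\1", f[9])
    if (identical(id, f[9])) id <- sprintf("gene_line%d", i)
    tibble(gene_id = id, seq_id = f[1], start = start - 1L, end = end,
           strand = f[7])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) return(empty)
  dplyr::arrange(out, .data$seq_id, .data$start)
}

#' Write gene models as GFF3
#'
#' @param genes Gene-model tibble (0-based half-open internal
#'   coordinates; written back as 1-based inclusive GFF3).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  body <- sprintf("%s\tzfscreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  genes$seq_id, genes$start + 1L, genes$end,
                  genes$strand, genes$gene_id)
  writeLines(c("##gff-version 3", body), path)
  invisible(path)
}

#' Extract strand-aware gene flanks
#'
#' For a + strand gene, the upstream flank is `[start - flank, start)`
#' and the downstream flank `[end, end + flank)`; for a - strand gene the
#' intervals are mirrored and the sequence is reverse-complemented so it
#' reads 5' to 3' relative to the gene. Flanks are clipped at contig
#' boundaries and flagged `truncated` when clipped. Flanks are not
#' trimmed when they overlap neighbouring genes.
#'
#' @param genome Named character vector of contig sequences or a
#'   `Biostrings::DNAStringSet`.
#' @param genes Gene-model tibble from [read_gene_models()].
#' @param flank Flank size in bp (default 2000).
#' @return Tibble with columns `gene_id`, `kind` (`"upstream"` /
#'   `"downstream"`), `seq_id`, `start`, `end` (0-based half-open genomic
#'   interval), `strand`, `sequence` (gene-oriented 5'->3'),
#'   `truncated`.
#' @export
extract_flanks <- function(genome, genes, flank = 2000) {
  genome <- as_named_dna(genome)
  missing <- setdiff(unique(genes$seq_id), names(genome))
  if (length(missing) > 0L) {
    bad <- genes$gene_id[genes$seq_id %in% missing]
    abort(sprintf("contig(s) missing from genome for gene(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  clen <- nchar(genome)
  one <- function(gene_id, seq_id, start, end, strand) {
    L <- clen[[seq_id]]
    if (strand == "+") {
      iv <- list(upstream = c(start - flank, start),
                 downstream = c(end, end + flank))
    } else {
      iv <- list(upstream = c(end, end + flank),
                 downstream = c(start - flank, start))
    }
    purrr::imap(iv, function(r, kind) {
      s <- max(0L, r[1])
      e <- min(L, r[2])
      trunc <- (s != r[1]) || (e != r[2])
      seq <- if (e > s) substr(genome[[seq_id]], s + 1L, e) else ""
      if (strand == "-") seq <- revcomp(seq)
      tibble(gene_id = gene_id, kind = kind, seq_id = seq_id,
             start = as.integer(s), end = as.integer(e), strand = strand,
             sequence = toupper(seq), truncated = trunc)
    }) |> dplyr::bind_rows()
  }
  purrr::pmap(genes[, c("gene_id", "seq_id", "start", "end", "strand")],
              one) |>
    dplyr::bind_rows()
}

#' Write flanks as FASTA (headers `geneID|up` / `geneID|down`) with a
#' BED companion
#'
#' @param flanks Tibble from [extract_flanks()].
#' @param fasta_path,bed_path Output paths (`NULL` to skip the BED).
#' @return `fasta_path`, invisibly.
#' @export
write_flanks_fasta <- function(flanks, fasta_path, bed_path = NULL) {
  tag <- ifelse(flanks$kind == "upstream", "up", "down")
  nm <- paste0(flanks$gene_id, "|", tag)
  seqs <- Biostrings::DNAStringSet(flanks$sequence)
  names(seqs) <- nm
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(bed_path)) {
    bed <- data.frame(flanks$seq_id, flanks$start, flanks$end, nm, 0L,
                      flanks$strand)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(fasta_path)
}

#' Longest open reading frame on the forward strand
#'
#' Scans the three forward reading frames for ATG-initiated,
#' stop-terminated open reading frames with no internal in-frame stop;
#' returns the longest (length includes the stop codon), ties broken by
#' the smallest start.
#'
#' @param transcript DNA string over A, C, G, T, N (sense strand).
#' @return One-row tibble `start`, `end` (0-based half-open), `length`
#'   in nucleotides; 0-row tibble when no ORF exists.
#' @examples
#' longest_orf("ATGAAATAA")  # length 9
#' @export
longest_orf <- function(transcript) {
  if (!is.character(transcript) || length(transcript) != 1L) {
    abort("transcript must be a single string")
  }
  s <- toupper(transcript)
  if (grepl("[^ACGTN]", s)) abort("transcript contains non-DNA letters")
  n <- nchar(s)
  empty <- tibble(start = integer(), end = integer(), length = integer())
  if (n < 6L) return(empty)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    open_at <- NA_integer_   # earliest ATG since last stop (codon index)
    for (k in seq_along(codons)) {
      if (codons[k] %in% stops) {
        if (!is.na(open_at)) {
          len <- (k - open_at + 1L) * 3L
          st <- starts[open_at] - 1L
          if (is.null(best) || len > best$length ||
              (len == best$length && st < best$start)) {
            best <- list(start = st, end = st + len, length = len)
          }
          open_at <- NA_integer_
        }
      } else if (is.na(open_at) && codons[k] == "ATG") {
        open_at <- k
      }
    }
  }
  if (is.null(best)) return(empty)
  tibble(start = best$start, end = best$end, length = best$length)
}
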