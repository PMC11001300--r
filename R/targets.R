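#' Scan gene flanks for motif occurrences
#'
#' Convenience wrapper: scans the `sequence` column of a flank table with
#' [scan_pwm()] and annotates each hit with the gene and flank kind it
#' fell in. Hit coordinates are flank-local (0-based offsets into the
#' gene-oriented flank sequence).
#'
#' @param flanks Tibble from [extract_flanks()].
#' @param x A `zf_pwm`.
#' @inheritParams scan_pwm
#' @return Tibble of hits with extra columns `gene_id` and `kind`.
#' @export
scan_flanks <- function(flanks, x, p_threshold = 1e-4, both_strands = TRUE,
                        background = NULL, granularity = 1000) {
  ok <- nchar(flanks$sequence) > 0L
  flanks <- flanks[ok, , drop = FALSE]
  if (nrow(flanks) == 0L) {
    return(tibble(gene_id = character(), kind = character(),
                  seq_id = character(), start = integer(),
                  strand = character(), score = numeric(),
                  pvalue = numeric(), qvalue = numeric(),
                  matched_seq = character()))
  }
  key <- paste0(flanks$gene_id, "|", ifelse(flanks$kind == "upstream",
                                            "up", "down"))
  seqs <- setNames(flanks$sequence, key)
  hits <- scan_pwm(seqs, x, p_threshold = p_threshold,
                   both_strands = both_strands, background = background,
                   granularity = granularity)
  meta <- tibble(seq_id = key, gene_id = flanks$gene_id,
                 kind = flanks$kind)
  dplyr::inner_join(hits, meta, by = "seq_id") |>
    dplyr::relocate("gene_id", "kind")
}

#' Count distinct genes carrying at least one motif hit
#'
#' @param hits Hit tibble carrying a `gene_id` column (e.g. from
#'   [scan_flanks()]).
#' @return Integer count of distinct `gene_id` values.
#' @export
count_genes_with_hits <- function(hits) {
  dplyr::n_distinct(hits$gene_id)
}

#' Read a differential-expression table
#'
#' TSV with header columns `gene_id`, `log2fc`, `pvalue`, `fdr`.
#'
#' @param path TSV path.
#' @return Tibble with those columns.
#' @export
read_deg_table <- function(path) {
  df <- as_tibble(read.delim(path, comment.char = "#"))
  need <- c("gene_id", "log2fc", "pvalue", "fdr")
  if (!all(need %in% names(df))) {
    abort(paste("DEG table must have columns:", paste(need, collapse = ", ")))
  }
  df
}

#' Nominate candidate direct targets
#'
#' Intersects flank motif hits with a differential-expression table: a
#' gene is nominated iff it has at least one flank hit and is a
#' significant DEG (|log2fc| >= `fc_threshold` and fdr <=
#' `fdr_threshold`). Genes with hits but absent from the DEG table are
#' carried with `significant = FALSE` and are never nominated.
#'
#' @param hits Hit tibble with `gene_id`, `kind`, `pvalue` columns (from
#'   [scan_flanks()]).
#' @param degs DEG tibble with `gene_id`, `log2fc`, `pvalue`, `fdr`.
#' @param fc_threshold Minimum |log2 fold change| (default 1).
#' @param fdr_threshold Maximum FDR (default 0.05).
#' @return Tibble with one row per gene in the union of the two inputs:
#'   `gene_id`, `n_hits_up`, `n_hits_down`, `best_pvalue`, `log2fc`,
#'   `fdr`, `significant`, `nominated`, sorted by (best_pvalue, gene_id).
#' @export
nominate_targets <- function(hits, degs, fc_threshold = 1,
                             fdr_threshold = 0.05) {
  if (anyDuplicated(degs$gene_id)) {
    dup <- unique(degs$gene_id[duplicated(degs$gene_id)])
    abort(paste("duplicate gene_id rows in DEG table:",
                paste(dup, collapse = ", ")))
  }
  hit_sum <- hits |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_hits_up = sum(.data$kind == "upstream"),
      n_hits_down = sum(.data$kind == "downstream"),
      best_pvalue = min(.data$pvalue),
      .groups = "drop"
    )
  out <- dplyr::full_join(hit_sum, degs, by = "gene_id",
                          suffix = c("", ".deg")) |>
    dplyr::mutate(
      n_hits_up = dplyr::coalesce(.data$n_hits_up, 0L),
      n_hits_down = dplyr::coalesce(.data$n_hits_down, 0L),
      significant = !is.na(.data$fdr) &
        abs(.data$log2fc) >= .env$fc_threshold &
        .data$fdr <= .env$fdr_threshold,
      nominated = (.data$n_hits_up + .data$n_hits_down >= 1L) &
        .data$significant
    ) |>
    dplyr::select("gene_id", "n_hits_up", "n_hits_down", "best_pvalue",
                  "log2fc", "fdr", "significant", "nominated")
  dplyr::arrange(out, .data$best_pvalue, .data$gene_id)
}

#' Write target calls with a summary block
#'
#' Writes the TSV of target calls preceded by `#`-prefixed summary lines
#' (total genes, genes with hits, significant DEGs, nominated).
#'
#' @param targets Tibble from [nominate_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_tsv <- function(targets, path) {
  summary <- c(
    sprintf("# total_genes\t%d", nrow(targets)),
    sprintf("# genes_with_hits\t%d",
            sum(targets$n_hits_up + targets$n_hits_down >= 1L)),
    sprintf("# significant_degs\t%d", sum(targets$significant)),
    sprintf("# nominated\t%d", sum(targets$nominated))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(summary, con)
  write.table(targets, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
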