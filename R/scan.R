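#' Exact p-values for PWM log-odds scores
#'
#' Builds the exact null distribution of the log-odds score of a random
#' width-W word drawn from the background model, by dynamic-programming
#' convolution of the per-column score distributions. Equal scores are
#' merged at a resolution of 1e-9 bits, so the distribution is exact for
#' any PWM of practical width; `granularity` only caps the support size
#' for very wide, ill-conditioned motifs.
#'
#' @param x A `zf_pwm`.
#' @param granularity Minimum number of score bins per column retained if
#'   the exact support has to be coarsened (only for supports beyond
#'   5e5 values). Must be >= 100.
#' @return An object of class `pwm_null` with elements `lodds` (4 x W
#'   log2-odds matrix), `scores` (sorted achievable scores), `tail`
#'   (P(S >= score)), and `pvalue(s)`, a right-continuous non-increasing
#'   step function with `pvalue(min score) = 1`.
#' @export
exact_pvalues <- function(x, granularity = 1000) {
  stopifnot(inherits(x, "zf_pwm"))
  if (granularity < 100) abort("granularity must be >= 100")
  lo <- log_odds(x)
  bg <- adjust_probs(x$background, x$pseudocount)
  # DP over columns; support merged on 1e-9-rounded score keys
  sc <- 0
  pr <- 1
  for (j in seq_len(x$width)) {
    new_sc <- as.numeric(outer(lo[, j], sc, "+"))
    new_pr <- as.numeric(outer(bg, pr, "*"))
    key <- round(new_sc, 9)
    agg <- rowsum(new_pr, group = key)
    sc <- as.numeric(rownames(agg))
    pr <- as.numeric(agg)
    if (length(sc) > 5e5) {
      bins <- granularity * x$width
      cut_key <- round((sc - min(sc)) / (max(sc) - min(sc)) * bins)
      agg <- rowsum(pr, group = cut_key)
      keep <- as.integer(rownames(agg))
      sc <- min(sc) + keep / bins * (max(sc) - min(sc))
      pr <- as.numeric(agg)
    }
    o <- order(sc)
    sc <- sc[o]
    pr <- pr[o]
  }
  tail_p <- rev(cumsum(rev(pr)))
  scores <- round(sc, 9)
  pv <- function(s) {
    idx <- findInterval(round(s, 9) - 1e-10, scores)
    out <- ifelse(idx >= length(scores), tail_p[length(scores)],
                  tail_p[idx + 1L])
    out[idx >= length(scores) &
          round(s, 9) - 1e-10 > scores[length(scores)]] <- 0
    out
  }
  structure(list(lodds = lo, scores = scores, tail = tail_p, pvalue = pv,
                 background = bg, width = x$width),
            class = "pwm_null")
}

# pseudocount-adjusted probabilities, renormalized
adjust_probs <- function(p, pseudocount) {
  (p + pseudocount) / (1 + 4 * pseudocount)
}

log_odds <- function(x) {
  p <- adjust_probs(x$probs, x$pseudocount)
  bg <- adjust_probs(x$background, x$pseudocount)
  if (any(p == 0) || any(bg == 0)) {
    abort(paste0("invalid configuration: zero probability with ",
                 "pseudocount 0 gives log(0); use pseudocount > 0"))
  }
  round(log2(p / bg), 9)
}

#' Scan DNA sequences for PWM matches
#'
#' FIMO-style scan: every window of width `pwm$width` on the forward (and
#' optionally reverse) strand is scored as the sum of per-position
#' log2-odds against a 0-order background model; windows whose exact
#' p-value is at most `p_threshold` are reported. Windows containing N
#' are skipped. Minus-strand hits are reported in forward-strand
#' coordinates (start of the leftmost base); `matched_seq` is the hit's
#' own (sense) strand.
#'
#' @param sequences Named character vector of DNA sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param x A `zf_pwm`.
#' @param p_threshold Report windows with p-value <= this (default 1e-4).
#' @param both_strands Scan the reverse strand as well (default TRUE).
#' @param background `NULL` (default) to estimate a 0-order background
#'   from `sequences` (uniform fallback), `"pwm"` to keep the PWM's own
#'   background, or a length-4 numeric vector.
#' @param granularity Passed to [exact_pvalues()].
#' @return Tibble with columns `seq_id`, `start` (0-based), `strand`,
#'   `score` (bits), `pvalue`, `qvalue` (Benjamini-Hochberg over all
#'   scanned windows), `matched_seq`; sorted by (seq_id, start, strand).
#' @export
scan_pwm <- function(sequences, x, p_threshold = 1e-4, both_strands = TRUE,
                     background = NULL, granularity = 1000) {
  stopifnot(inherits(x, "zf_pwm"))
  sequences <- as_named_dna(sequences)
  if (is.null(background)) {
    background <- estimate_background(sequences)
  } else if (identical(background, "pwm")) {
    background <- x$background
  }
  x <- pwm(x$probs, id = x$id, background = background,
           pseudocount = x$pseudocount)
  null <- exact_pvalues(x, granularity)
  w <- x$width
  lo_f <- null$lodds
  lo_r <- lo_f[COMP_IDX, rev(seq_len(w)), drop = FALSE]

  one_strand <- function(enc, lo) {
    n <- length(enc) - w + 1L
    if (n < 1L) return(numeric(0))
    s <- numeric(n)
    for (j in seq_len(w)) {
      col <- lo[, j][enc[j:(j + n - 1L)]]
      s <- s + ifelse(is.na(col), NA_real_, col)
    }
    s
  }

  rows <- purrr::imap(sequences, function(seq, id) {
    enc <- encode_dna(seq)
    sf <- one_strand(enc, lo_f)
    res <- list(tibble(seq_id = id, start = seq_along(sf) - 1L,
                       strand = "+", score = sf))
    if (both_strands) {
      sr <- one_strand(enc, lo_r)
      res <- c(res, list(tibble(seq_id = id, start = seq_along(sr) - 1L,
                                strand = "-", score = sr)))
    }
    dplyr::bind_rows(res)
  })
  all <- dplyr::bind_rows(rows)
  if (nrow(all) == 0L) {
    return(tibble(seq_id = character(), start = integer(),
                  strand = character(), score = numeric(),
                  pvalue = numeric(), qvalue = numeric(),
                  matched_seq = character()))
  }
  all <- dplyr::filter(all, !is.na(.data$score))
  all$pvalue <- null$pvalue(all$score)
  all$qvalue <- p.adjust(all$pvalue, method = "BH")
  hits <- dplyr::filter(all, .data$pvalue <= .env$p_threshold)
  hits$matched_seq <- vapply(seq_len(nrow(hits)), function(i) {
    s <- substr(sequences[[hits$seq_id[i]]], hits$start[i] + 1L,
                hits$start[i] + w)
    if (hits$strand[i] == "-") revcomp(s) else toupper(s)
  }, character(1))
  dplyr::arrange(hits, .data$seq_id, .data$start, .data$strand)
}

as_named_dna <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (!is.character(sequences)) abort("sequences must be character or DNAStringSet")
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  sequences
}

estimate_background <- function(sequences) {
  counts <- colSums(do.call(rbind, lapply(sequences, function(s) {
    v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    vapply(DNA_BASES, function(b) sum(v == b), numeric(1))
  })))
  if (sum(counts) == 0) return(rep(0.25, 4))
  as.numeric(counts / sum(counts))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjusted p-values (a thin wrapper over
#' `stats::p.adjust(method = "BH")` with input validation).
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return q-values of the same length; empty input gives empty output.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Write motif hits as TSV or BED
#'
#' TSV columns: seq_id, start, stop, strand, score, pvalue, qvalue,
#' matched_seq (0-based half-open). BED is 6-column with the log-odds
#' score rescaled linearly to 0-1000 over the observed score range.
#'
#' @param hits Tibble from [scan_pwm()].
#' @param path Output path.
#' @param name Feature name used in the BED name column.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  w <- if (nrow(hits)) nchar(hits$matched_seq[1]) else 0L
  out <- dplyr::mutate(hits, stop = .data$start + w, .after = "start")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_hits_bed <- function(hits, path, name = "motif") {
  if (nrow(hits) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  w <- nchar(hits$matched_seq[1])
  rng <- range(hits$score, finite = TRUE)
  scaled <- if (nrow(hits) == 0L || diff(rng) == 0) {
    rep(1000L, nrow(hits))
  } else {
    as.integer(round(1000 * (hits$score - rng[1]) / diff(rng)))
  }
  bed <- data.frame(hits$seq_id, hits$start, hits$start + w, name,
                    scaled, hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
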