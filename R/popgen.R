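#' Construct a two-population haplotype matrix
#'
#' @param alleles Samples x sites matrix over {0, 1, NA}.
#' @param positions Strictly increasing 0-based site positions (length =
#'   ncol(alleles)).
#' @param pops Character vector of population labels, one per sample
#'   (two distinct labels for Fst).
#' @param sample_ids Optional sample names (default from rownames or
#'   `hap<i>`).
#' @param seq_id Contig/chromosome name the positions refer to.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, positions, pops, sample_ids = NULL,
                             seq_id = "chr") {
  alleles <- as.matrix(alleles)
  if (length(positions) != ncol(alleles)) {
    abort("positions length must equal the number of sites")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    abort("positions must be strictly increasing")
  }
  if (length(pops) != nrow(alleles)) {
    abort("pops length must equal the number of samples")
  }
  if (!all(alleles %in% c(0L, 1L, NA))) {
    abort("alleles must be 0, 1 or NA")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(alleles)
    if (is.null(sample_ids)) sample_ids <- paste0("hap", seq_len(nrow(alleles)))
  }
  structure(list(alleles = alleles, positions = as.numeric(positions),
                 pops = as.character(pops), sample_ids = sample_ids,
                 seq_id = seq_id),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("<haplotype_matrix> %d haplotypes x %d sites on %s\n",
              nrow(x$alleles), ncol(x$alleles), x$seq_id))
  print(table(x$pops))
  invisible(x)
}

#' Read biallelic haplotypes from a minimal VCF
#'
#' Reads GT fields with `vcfR`; diploid unphased genotypes are split
#' into two haplotypes per sample. Multi-allelic sites and sites without
#' a parseable GT are skipped with a warning. Missing alleles become NA.
#'
#' @param vcf_path VCF file path.
#' @param pop_path Two-column TSV (no header): sample, population.
#' @return A `haplotype_matrix`.
#' @export
read_haplotypes_vcf <- function(vcf_path, pop_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warn(sprintf("%d multi-allelic site(s) skipped", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  pops_df <- read.delim(pop_path, header = FALSE,
                        col.names = c("sample", "pop"))
  samples <- colnames(gt)
  pop_map <- setNames(pops_df$pop, pops_df$sample)
  if (!all(samples %in% names(pop_map))) {
    abort("population file missing some VCF samples")
  }
  # split "a/b" or "a|b" into two haplotypes per sample
  parse_allele <- function(x) {
    x[x == "."] <- NA
    suppressWarnings(as.integer(x))
  }
  toks <- strsplit(as.vector(gt), "[/|]")
  a1 <- parse_allele(vapply(toks, function(t) t[1], character(1)))
  a2 <- parse_allele(vapply(toks, function(t) if (length(t) > 1) t[2] else NA_character_,
                            character(1)))
  n_sites <- nrow(gt)
  m1 <- matrix(a1, nrow = n_sites)
  m2 <- matrix(a2, nrow = n_sites)
  alle <- rbind(t(m1), t(m2))
  ids <- c(paste0(samples, "_1"), paste0(samples, "_2"))
  pops <- pop_map[c(samples, samples)]
  pos <- as.numeric(fix[, "POS"]) - 1  # VCF is 1-based
  o <- order(pos)
  haplotype_matrix(alle[, o, drop = FALSE], pos[o], pops,
                   sample_ids = ids, seq_id = fix[1, "CHROM"])
}

#' Read haplotypes from a 0/1 matrix TSV
#'
#' Layout: first column `sample`, second `pop`, remaining columns one
#' per site named by 0-based position; cells 0/1/NA.
#'
#' @param path TSV path.
#' @param seq_id Contig name.
#' @return A `haplotype_matrix`.
#' @export
read_haplotypes_tsv <- function(path, seq_id = "chr") {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  alle <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(alle) <- "integer"
  haplotype_matrix(alle, as.numeric(colnames(alle)), df$pop,
                   sample_ids = df$sample, seq_id = seq_id)
}

# per-site unbiased heterozygosity 2*p*q*n/(n-1); NA where n < 2
site_het <- function(m) {
  n <- colSums(!is.na(m))
  p <- colMeans(m, na.rm = TRUE)
  ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)
}

#' Nucleotide diversity of one population over a window
#'
#' Mean pairwise differences per bp: the sum over sites of the unbiased
#' per-site heterozygosity `2*p*q*n/(n-1)` divided by the window length.
#' Missing calls are excluded per site (per-site n).
#'
#' @param m Haplotypes x sites matrix over {0, 1, NA} (one population).
#' @param window_length Window length in bp (> 0).
#' @return Per-site diversity (>= 0), or NA when no site has >= 2
#'   non-missing haplotypes.
#' @export
nucleotide_diversity <- function(m, window_length) {
  if (window_length <= 0) abort("window_length must be positive")
  m <- as.matrix(m)
  if (ncol(m) == 0L) return(0)
  h <- site_het(m)
  if (all(is.na(h))) return(NA_real_)
  sum(h, na.rm = TRUE) / window_length
}

#' Hudson's Fst between two populations over a window
#'
#' Ratio-of-averages estimator: `1 - mean(Hw) / mean(Hb)` across sites,
#' where Hw is the mean of the two unbiased within-population
#' heterozygosities and `Hb = pA*(1-pB) + pB*(1-pA)` the
#' between-population heterozygosity. Sites monomorphic across both
#' populations (Hb = 0 and Hw = 0) are excluded; if no informative site
#' remains the estimate is NA.
#'
#' @param mA,mB Haplotypes x sites matrices (same sites) for the two
#'   populations.
#' @return Fst in approximately [-0.1, 1], or NA when undefined.
#' @export
hudson_fst <- function(mA, mB) {
  mA <- as.matrix(mA)
  mB <- as.matrix(mB)
  if (ncol(mA) != ncol(mB)) abort("populations must share the same sites")
  if (ncol(mA) == 0L) return(NA_real_)
  hA <- site_het(mA)
  hB <- site_het(mB)
  pA <- colMeans(mA, na.rm = TRUE)
  pB <- colMeans(mB, na.rm = TRUE)
  hw <- (hA + hB) / 2
  hb <- pA * (1 - pB) + pB * (1 - pA)
  keep <- !is.na(hw) & !is.na(hb) & !(hb == 0 & hw == 0)
  if (!any(keep) || mean(hb[keep]) == 0) return(NA_real_)
  1 - mean(hw[keep]) / mean(hb[keep])
}

#' Sliding-window diversity and differentiation
#'
#' Tiles `region` with windows of `window` bp advanced by `step` bp and
#' computes per-window nucleotide diversity for each population and
#' Hudson's Fst between them. Windows with no sites carry `n_sites = 0`
#' and NA statistics (distinct from a monomorphic window, which carries
#' pi = 0).
#'
#' @param hm A `haplotype_matrix` with exactly two population labels.
#' @param region Length-2 numeric `c(start, end)` (0-based half-open);
#'   default spans the observed positions.
#' @param window,step Window and step sizes in bp; `window >= step >= 1`.
#' @return Tibble with columns `seq_id`, `start`, `end`, `n_sites`,
#'   `pi_A`, `pi_B`, `fst` (A and B are the sorted population labels).
#' @export
sliding_windows <- function(hm, region = NULL, window = 5000, step = 1000) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  if (step < 1 || window < step) abort("need window >= step >= 1")
  labs <- sort(unique(hm$pops))
  if (length(labs) != 2L) abort("exactly two populations required")
  if (is.null(region)) {
    region <- c(0, max(hm$positions) + 1)
  }
  if (region[2] <= region[1]) abort("empty region")
  if (region[1] > max(hm$positions) || region[2] <= min(hm$positions)) {
    warn("region lies outside the observed position range")
    return(tibble(seq_id = character(), start = numeric(), end = numeric(),
                  n_sites = integer(), pi_A = numeric(), pi_B = numeric(),
                  fst = numeric()))
  }
  starts <- seq(region[1], by = step,
                length.out = max(1, floor((region[2] - region[1] - window) /
                                            step) + 1))
  A <- hm$alleles[hm$pops == labs[1], , drop = FALSE]
  B <- hm$alleles[hm$pops == labs[2], , drop = FALSE]
  rows <- purrr::map(starts, function(s) {
    e <- s + window
    in_w <- hm$positions >= s & hm$positions < e
    ns <- sum(in_w)
    if (ns == 0L) {
      return(tibble(seq_id = hm$seq_id, start = s, end = e, n_sites = 0L,
                    pi_A = NA_real_, pi_B = NA_real_, fst = NA_real_))
    }
    tibble(seq_id = hm$seq_id, start = s, end = e, n_sites = ns,
           pi_A = nucleotide_diversity(A[, in_w, drop = FALSE], window),
           pi_B = nucleotide_diversity(B[, in_w, drop = FALSE], window),
           fst = hudson_fst(A[, in_w, drop = FALSE],
                            B[, in_w, drop = FALSE]))
  })
  dplyr::bind_rows(rows)
}

#' Empirical top-quantile threshold for window statistics
#'
#' Linear-interpolation empirical quantile (type 7) of a window
#' statistic; windows at or above the threshold are the outliers (e.g.
#' the top-5% fixation level with `q = 0.95`).
#'
#' @param stats Tibble from [sliding_windows()].
#' @param field Which statistic to threshold: `"fst"`, `"pi_A"` or
#'   `"pi_B"`.
#' @param q Quantile in (0, 1) (default 0.95).
#' @return The threshold value.
#' @export
top_quantile_threshold <- function(stats, field = c("fst", "pi_A", "pi_B"),
                                   q = 0.95) {
  field <- match.arg(field)
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  v <- stats[[field]]
  v <- v[!is.na(v)]
  if (length(v) == 0L) abort("no defined values for the chosen field")
  unname(quantile(v, q, type = 7))
}

#' Flag outlier windows at a top-quantile threshold
#'
#' @inheritParams top_quantile_threshold
#' @return `stats` with added logical column `outlier` (value >=
#'   threshold) and attribute `"threshold"`.
#' @export
flag_outlier_windows <- function(stats, field = c("fst", "pi_A", "pi_B"),
                                 q = 0.95) {
  field <- match.arg(field)
  thr <- top_quantile_threshold(stats, field, q)
  out <- dplyr::mutate(stats, outlier = !is.na(.data[[field]]) &
                         .data[[field]] >= thr)
  attr(out, "threshold") <- thr
  out
}

#' Write window statistics as TSV, and outlier windows as BED
#'
#' @param stats Tibble from [sliding_windows()] (for the BED writer, from
#'   [flag_outlier_windows()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_tsv <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_tsv
#' @export
write_outliers_bed <- function(stats, path) {
  if (!"outlier" %in% names(stats)) abort("run flag_outlier_windows() first")
  o <- stats[stats$outlier, , drop = FALSE]
  bed <- data.frame(o$seq_id, format(o$start, scientific = FALSE, trim = TRUE),
                    format(o$end, scientific = FALSE, trim = TRUE))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Plot sliding-window diversity and differentiation tracks
#'
#' Faceted line tracks of per-window pi (both populations) and Fst along
#' the region, with a dashed line at the top-`1-q` quantile of Fst.
#'
#' @param stats Tibble from [sliding_windows()].
#' @param q Quantile for the dashed Fst threshold (default 0.95).
#' @return A ggplot object.
#' @export
plot_window_stats <- function(stats, q = 0.95) {
  thr <- tryCatch(top_quantile_threshold(stats, "fst", q),
                  error = function(e) NA_real_)
  long <- tidyr::pivot_longer(stats, c("pi_A", "pi_B", "fst"),
                              names_to = "stat", values_to = "value")
  long$panel <- ifelse(long$stat == "fst", "Fst", "pi")
  hline <- tibble(panel = "Fst", thr = thr)
  ggplot2::ggplot(long, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                     y = .data$value,
                                     colour = .data$stat)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(data = hline[!is.na(hline$thr), ],
                        ggplot2::aes(yintercept = .data$thr),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
}
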