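#' Relative expression from a single Delta-Delta-Ct
#'
#' `ddCt = (target - ref) - (target_cal - ref_cal)`; returns
#' `R = 2^-ddCt`.
#'
#' @param target_ct,ref_ct Ct of target and reference gene in the
#'   condition of interest.
#' @param target_ct_calibrator,ref_ct_calibrator Ct of target and
#'   reference gene in the calibrator condition.
#' @return Fold change R (> 0).
#' @examples
#' delta_delta_ct(20, 15, 22, 15)  # 4
#' @export
delta_delta_ct <- function(target_ct, ref_ct, target_ct_calibrator,
                           ref_ct_calibrator) {
  stopifnot(is.finite(target_ct), is.finite(ref_ct),
            is.finite(target_ct_calibrator), is.finite(ref_ct_calibrator))
  ddct <- (target_ct - ref_ct) - (target_ct_calibrator - ref_ct_calibrator)
  2^(-ddct)
}

#' Read a long-format Ct table
#'
#' TSV with header columns `sample`, `group`, `gene`, `replicate`, `ct`.
#'
#' @param path TSV path.
#' @return Tibble with those columns.
#' @export
read_ct_table <- function(path) {
  df <- as_tibble(read.delim(path, comment.char = "#"))
  need <- c("sample", "group", "gene", "replicate", "ct")
  if (!all(need %in% names(df))) {
    abort(paste("Ct table must have columns:", paste(need, collapse = ", ")))
  }
  df
}

#' Group-level relative expression by 2^-ddCt
#'
#' Technical replicates are averaged per (sample, gene); each sample's
#' dCt = mean target Ct - mean reference Ct; the calibrator dCt is the
#' mean dCt of the calibrator group; per-sample fold changes
#' `R = 2^-(dCt - calibrator dCt)` are summarised per group as mean +- SD.
#' Significance between each group and the calibrator is tested on the
#' dCt scale (approximately normal) with Student's t test (equal
#' variances by default; `var_equal = FALSE` gives Welch) or a paired t
#' test pairing samples by sorted sample id.
#'
#' @param records Ct tibble (`sample`, `group`, `gene`, `replicate`,
#'   `ct`), e.g. from [read_ct_table()].
#' @param gene Target gene name.
#' @param ref_gene Reference gene used for normalization (e.g. RpL3).
#' @param calibrator_group Group whose mean dCt defines R = 1.
#' @param test `"student"` (two-sample) or `"paired"`.
#' @param var_equal Equal-variance Student's t (default TRUE).
#' @return A `relexpr` tibble: one row per group with `gene`, `group`,
#'   `r` (mean fold change), `sd`, `n`, `t_stat`, `pvalue` (NA for the
#'   calibrator row and for groups with < 2 samples).
#' @export
group_relexpr <- function(records, gene, ref_gene,
                          calibrator_group, test = c("student", "paired"),
                          var_equal = TRUE) {
  test <- match.arg(test)
  if (!calibrator_group %in% records$group) {
    abort(sprintf("calibrator group '%s' not present", calibrator_group))
  }
  per_sample <- records |>
    dplyr::filter(.data$gene %in% c(.env$gene, .env$ref_gene)) |>
    dplyr::group_by(.data$sample, .data$group, .data$gene) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "ct")
  if (!ref_gene %in% names(per_sample)) {
    abort(sprintf("reference gene '%s' not measured", ref_gene))
  }
  miss <- is.na(per_sample[[ref_gene]]) | is.na(per_sample[[gene]])
  if (any(miss)) {
    warn(sprintf("%d sample(s) dropped: missing %s or %s", sum(miss),
                 ref_gene, gene))
    per_sample <- per_sample[!miss, , drop = FALSE]
  }
  per_sample$dct <- per_sample[[gene]] - per_sample[[ref_gene]]
  cal_dct <- per_sample$dct[per_sample$group == calibrator_group]
  per_sample$r <- 2^(-(per_sample$dct - mean(cal_dct)))
  out <- per_sample |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(gene = .env$gene, sd = stats::sd(.data$r),
                     r = mean(.data$r), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::select("gene", "group", "r", "sd", "n")
  tt <- purrr::map(out$group, function(g) {
    x <- per_sample$dct[per_sample$group == g]
    if (g == calibrator_group || length(x) < 2L || length(cal_dct) < 2L) {
      return(c(NA_real_, NA_real_))
    }
    if (stats::sd(x) == 0 && stats::sd(cal_dct) == 0) {
      # degenerate noise-free data: identical sets give t = 0, p = 1
      if (isTRUE(all.equal(mean(x), mean(cal_dct)))) return(c(0, 1))
      return(c(sign(mean(x) - mean(cal_dct)) * Inf, 0))
    }
    res <- if (test == "paired") {
      if (length(x) != length(cal_dct)) {
        warn("paired test needs equal group sizes; p omitted")
        return(c(NA_real_, NA_real_))
      }
      o1 <- order(per_sample$sample[per_sample$group == g])
      o2 <- order(per_sample$sample[per_sample$group == calibrator_group])
      dif <- x[o1] - cal_dct[o2]
      if (stats::sd(dif) == 0) {
        return(if (mean(dif) == 0) c(0, 1) else c(sign(mean(dif)) * Inf, 0))
      }
      t.test(x[o1], cal_dct[o2], paired = TRUE)
    } else {
      t.test(x, cal_dct, var.equal = var_equal)
    }
    c(unname(res$statistic), res$p.value)
  })
  out$t_stat <- purrr::map_dbl(tt, 1)
  out$pvalue <- purrr::map_dbl(tt, 2)
  class(out) <- c("relexpr", class(out))
  attr(out, "calibrator") <- calibrator_group
  attr(out, "ref_gene") <- ref_gene
  out
}

#' @export
#' @method glance relexpr
glance.relexpr <- function(x, ...) {
  tibble(gene = x$gene[1], calibrator = attr(x, "calibrator"),
         ref_gene = attr(x, "ref_gene"), n_groups = nrow(x),
         max_fold_change = max(x$r), min_pvalue = suppressWarnings(
           min(x$pvalue, na.rm = TRUE)))
}

#' Bar plot of relative expression with SD error bars
#'
#' @param object A `relexpr` tibble from [group_relexpr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot relexpr
autoplot.relexpr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$r)) +
    ggplot2::geom_col(fill = "grey40", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r - .data$sd,
                                        ymax = .data$r + .data$sd),
                           width = 0.2) +
    ggplot2::labs(y = expression(2^{-Delta * Delta * "Ct"}),
                  x = NULL, title = object$gene[1]) +
    ggplot2::theme_minimal()
}
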