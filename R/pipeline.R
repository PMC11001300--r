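#' Run the end-to-end target-screening pipeline
#'
#' Chains flank extraction, motif scanning and DEG intersection: extract
#' the 2-kb (by default) upstream/downstream flank of every gene, scan
#' both strands of every flank for the motif at the exact-p-value
#' threshold, and nominate genes that both carry a hit and are
#' significant DEGs.
#'
#' @param genome Named character vector of contigs or
#'   `Biostrings::DNAStringSet`.
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param degs DEG tibble (`gene_id`, `log2fc`, `pvalue`, `fdr`).
#' @param x Motif (`zf_pwm`), default the packaged Bm-mamo-S fixture.
#' @inheritParams extract_flanks
#' @inheritParams scan_pwm
#' @inheritParams nominate_targets
#' @return A `zf_pipeline` list with elements `flanks`, `hits`,
#'   `targets`, `summary` (one-row tibble) and `params`.
#' @export
run_pipeline <- function(genome, genes, degs, x = mamo_pwm(),
                         flank = 2000, p_threshold = 1e-4,
                         both_strands = TRUE, fc_threshold = 1,
                         fdr_threshold = 0.05) {
  flanks <- extract_flanks(genome, genes, flank = flank)
  hits <- scan_flanks(flanks, x, p_threshold = p_threshold,
                      both_strands = both_strands)
  targets <- nominate_targets(hits, degs, fc_threshold = fc_threshold,
                              fdr_threshold = fdr_threshold)
  summary <- tibble(
    genes_scanned = nrow(genes),
    genes_with_hits = count_genes_with_hits(hits),
    significant_degs = sum(targets$significant),
    nominated = sum(targets$nominated)
  )
  structure(
    list(flanks = flanks, hits = hits, targets = targets,
         summary = summary,
         params = list(motif = x$id, flank = flank,
                       p_threshold = p_threshold,
                       both_strands = both_strands,
                       fc_threshold = fc_threshold,
                       fdr_threshold = fdr_threshold)),
    class = "zf_pipeline")
}

#' @export
print.zf_pipeline <- function(x, ...) {
  cat("<zf_pipeline>\n")
  p <- x$params
  cat(sprintf("  motif %s | flank %d bp | p <= %g | |log2FC| >= %g, fdr <= %g\n",
              p$motif, p$flank, p$p_threshold, p$fc_threshold,
              p$fdr_threshold))
  print(x$summary)
  invisible(x)
}

#' @export
#' @method tidy zf_pipeline
tidy.zf_pipeline <- function(x, ...) x$targets

#' @export
#' @method glance zf_pipeline
glance.zf_pipeline <- function(x, ...) x$summary

#' Plot per-gene flank hit counts against differential expression
#'
#' @param object A `zf_pipeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot zf_pipeline
autoplot.zf_pipeline <- function(object, ...) {
  df <- object$targets
  df$n_hits <- df$n_hits_up + df$n_hits_down
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$n_hits,
                                   colour = .data$nominated)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "log2 fold change", y = "flank motif hits") +
    ggplot2::theme_minimal()
}
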