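#' Simulate a toy genome with binding sites planted in gene flanks
#'
#' Generates one contig of i.i.d. background sequence with `n_genes`
#' equally spaced gene models, then plants one binding site per "true
#' target" gene: the site is sampled column-wise from the motif at
#' `site_strength` consensus probability (1.0 gives the exact
#' consensus), placed at a uniform offset inside a randomly chosen 2-kb
#' flank (avoiding the outer 10 bp so no site is clipped), on a random
#' strand. Deterministic given `seed`.
#'
#' @param n_genes Number of gene models.
#' @param contig_length Contig length in bp; must fit
#'   `n_genes * (gene_length + 2 * flank)`.
#' @param flank Flank size in bp (default 2000).
#' @param x Motif (`zf_pwm`) whose consensus is planted (default
#'   [mamo_pwm()]).
#' @param n_true_targets How many genes receive a planted site.
#' @param site_strength Consensus probability used when sampling planted
#'   sites (default 1.0 = exact consensus).
#' @param gene_length Gene body length in bp (default 1000).
#' @param gc Background GC content (default 0.5).
#' @param seed Integer seed.
#' @return List with `genome` (named character vector of one contig),
#'   `genes` (gene-model tibble), and `truth` (list with
#'   `true_target_genes`, `planted_sites` tibble with flank-forward
#'   genomic offsets, and the generator parameters).
#' @export
simulate_genome <- function(n_genes = 20, contig_length = 200000,
                            flank = 2000, x = mamo_pwm(),
                            n_true_targets = 7, site_strength = 1.0,
                            gene_length = 1000, gc = 0.5, seed = 1) {
  if (n_true_targets < 0 || n_true_targets > n_genes) {
    abort("need 0 <= n_true_targets <= n_genes")
  }
  need <- n_genes * (gene_length + 2 * flank)
  if (need > contig_length) {
    abort(sprintf("invalid configuration: %d genes x %d bp do not fit in %d bp",
                  n_genes, gene_length + 2L * flank, contig_length))
  }
  set.seed(seed)
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  contig <- sample(DNA_BASES, contig_length, replace = TRUE, prob = base_p)
  spacing <- contig_length / n_genes
  starts <- as.integer(round(spacing * (seq_len(n_genes) - 1) +
                               (spacing - gene_length) / 2))
  genes <- tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    seq_id = "contig1",
    start = starts,
    end = starts + as.integer(gene_length),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
  targets <- sort(sample.int(n_genes, n_true_targets))
  w <- x$width
  site_pwm <- pwm_from_consensus(consensus(x), max(site_strength, 0.2501))
  planted <- purrr::map(targets, function(gi) {
    g <- genes[gi, ]
    kind <- sample(c("upstream", "downstream"), 1)
    left_of_gene <- (g$strand == "+") == (kind == "upstream")
    iv <- if (left_of_gene) c(g$start - flank, g$start) else c(g$end, g$end + flank)
    offset <- sample(seq.int(10L, flank - w - 10L), 1)
    pos <- iv[1] + offset  # 0-based genomic start of the site
    site <- if (site_strength >= 1) {
      consensus(x)
    } else {
      paste(DNA_BASES[apply(site_pwm$probs, 2, function(p) {
        sample.int(4, 1, prob = p)
      })], collapse = "")
    }
    strand <- sample(c("+", "-"), 1)
    inserted <- if (strand == "+") site else revcomp(site)
    contig[(pos + 1):(pos + w)] <<- strsplit(inserted, "")[[1]]
    tibble(gene_id = g$gene_id, kind = kind, offset = pos - iv[1],
           genomic_start = pos, strand = strand, site = site)
  })
  planted <- dplyr::bind_rows(planted)
  genome <- setNames(paste(contig, collapse = ""), "contig1")
  list(
    genome = genome,
    genes = genes,
    truth = list(
      true_target_genes = genes$gene_id[targets],
      planted_sites = planted,
      params = list(n_genes = n_genes, contig_length = contig_length,
                    flank = flank, motif = consensus(x),
                    site_strength = site_strength, seed = seed)
    )
  )
}

#' Simulate a differential-expression table with known perturbed genes
#'
#' Per gene, two groups of `n_reps` replicate log2 expression values are
#' drawn with Gaussian noise; genes in `truth$true_target_genes` receive
#' a mean shift of `effect_log2fc`, all others 0. log2 fold change, a
#' two-sample t test and Benjamini-Hochberg FDR are computed per gene.
#'
#' @param truth Truth list from [simulate_genome()] (or any list with a
#'   `true_target_genes` character vector).
#' @param all_genes Character vector of all gene ids.
#' @param effect_log2fc True log2 fold change of the perturbed genes
#'   (default 3).
#' @param replicate_noise_sd Replicate noise SD in log2 units (default
#'   0.2).
#' @param n_reps Replicates per group (default 3).
#' @param baseline Baseline mean log2 expression (default 8).
#' @param seed Integer seed.
#' @return DEG tibble (`gene_id`, `log2fc`, `pvalue`, `fdr`).
#' @export
simulate_deg_table <- function(truth, all_genes, effect_log2fc = 3,
                               replicate_noise_sd = 0.2, n_reps = 3,
                               baseline = 8, seed = 1) {
  if (effect_log2fc < 0) abort("effect_log2fc must be >= 0")
  if (n_reps < 2) abort("n_reps must be >= 2")
  set.seed(seed)
  is_target <- all_genes %in% truth$true_target_genes
  rows <- purrr::map2(all_genes, is_target, function(g, tgt) {
    ctrl <- rnorm(n_reps, baseline, replicate_noise_sd)
    cond <- rnorm(n_reps, baseline + if (tgt) effect_log2fc else 0,
                  replicate_noise_sd)
    tt <- t.test(cond, ctrl, var.equal = TRUE)
    tibble(gene_id = g, log2fc = mean(cond) - mean(ctrl),
           pvalue = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  out
}

#' Simulate two-population haplotypes with one differentiated window
#'
#' Background sites share allele frequencies drawn from a common
#' distribution in both populations; inside `diverged_window` the two
#' population frequencies are separated by `divergence_level` (1 gives
#' fixed differences). Sample sizes default to the 51 wild and 171
#' domestic haplotype panels of the motivating selection scan.
#'
#' @param n_a,n_b Haplotypes per population (defaults 51 and 171).
#' @param region_length Region length in bp (default 100000).
#' @param site_density Expected segregating sites per bp (default 0.002).
#' @param diverged_window `c(start, end)` 0-based half-open interval to
#'   differentiate, or `NULL` for none (default `c(40000, 50000)`).
#' @param divergence_level Allele-frequency separation inside the window
#'   in [0, 1] (default 0.8).
#' @param seed Integer seed.
#' @return A `haplotype_matrix` with populations `"A"` (wild-like) and
#'   `"B"` (domestic-like), carrying the truth parameters as attribute
#'   `"truth"`.
#' @export
simulate_haplotypes <- function(n_a = 51, n_b = 171, region_length = 100000,
                                site_density = 0.002,
                                diverged_window = c(40000, 50000),
                                divergence_level = 0.8, seed = 1) {
  if (divergence_level < 0 || divergence_level > 1) {
    abort("divergence_level must lie in [0, 1]")
  }
  set.seed(seed)
  n_sites <- max(2L, stats::rpois(1, region_length * site_density))
  positions <- sort(sample.int(region_length, n_sites)) - 1
  p0 <- runif(n_sites, 0.05, 0.95)
  pA <- p0
  pB <- p0
  if (!is.null(diverged_window)) {
    if (diverged_window[1] < 0 || diverged_window[2] > region_length) {
      abort("diverged_window must lie inside the region")
    }
    inw <- positions >= diverged_window[1] & positions < diverged_window[2]
    d <- divergence_level
    pA[inw] <- p0[inw] + d * (1 - p0[inw])  # pushed toward fixation of 1
    pB[inw] <- p0[inw] - d * p0[inw]        # pushed toward fixation of 0
  }
  drawn <- function(n, p) {
    matrix(rbinom(n * length(p), 1L, rep(p, each = n)), nrow = n)
  }
  alle <- rbind(drawn(n_a, pA), drawn(n_b, pB))
  hm <- haplotype_matrix(alle, positions,
                         pops = c(rep("A", n_a), rep("B", n_b)),
                         seq_id = "chr9")
  attr(hm, "truth") <- list(diverged_window = diverged_window,
                            divergence_level = divergence_level,
                            seed = seed)
  hm
}

#' Simulate a long-format qPCR Ct table with known fold changes
#'
#' The reference gene has a constant mean Ct across groups; each target
#' gene's Ct in a non-calibrator group is shifted by `-log2(fold
#' change)`. Each group has `n_reps` biological samples, each measured
#' in technical triplicate; every measurement carries independent
#' Gaussian noise of SD `noise_sd` cycles (0 gives noise-free tables).
#'
#' @param genes Character vector of target gene names.
#' @param groups Character vector of group names; the first is the
#'   calibrator.
#' @param fold_changes Numeric vector (recycled over genes) of true fold
#'   changes of each target in non-calibrator groups (> 0).
#' @param noise_sd Measurement noise SD in Ct cycles (default 0.1).
#' @param n_reps Biological samples per group (default 3).
#' @param ref_gene Reference gene name (default "RpL3").
#' @param seed Integer seed.
#' @return Ct tibble (`sample`, `group`, `gene`, `replicate`, `ct`) with
#'   attribute `"truth"` holding the fold changes.
#' @export
simulate_ct_table <- function(genes = "target1",
                              groups = c("control", "mutant"),
                              fold_changes = 4, noise_sd = 0.1,
                              n_reps = 3, ref_gene = "RpL3",
                              seed = 1) {
  if (any(fold_changes <= 0)) abort("fold_changes must be > 0")
  set.seed(seed)
  fold_changes <- rep_len(fold_changes, length(genes))
  base_ct <- setNames(20 + seq_along(genes) - 1, genes)
  rows <- list()
  for (gi in seq_along(groups)) {
    for (s in seq_len(n_reps)) {
      sample_id <- sprintf("%s_s%d", groups[gi], s)
      for (g in c(ref_gene, genes)) {
        mu <- if (g == ref_gene) 15 else {
          base_ct[[g]] - if (gi > 1) log2(fold_changes[[match(g, genes)]]) else 0
        }
        ct <- mu + rnorm(3, 0, noise_sd)
        rows[[length(rows) + 1L]] <- tibble(
          sample = sample_id, group = groups[gi], gene = g,
          replicate = 1:3, ct = ct)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- list(fold_changes = setNames(fold_changes, genes),
                             calibrator = groups[1], seed = seed)
  out
}

#' Write a simulated genome as FASTA
#'
#' @param genome Named character vector of contigs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
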