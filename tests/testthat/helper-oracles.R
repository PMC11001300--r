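# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately avoid the package's own code paths.

ZIF_FINGER <- "FQCRICMRNFSRSDHLTTHIRTHT"

rand_dna <- function(n, seed = NULL, letters = c("A", "C", "G", "T"),
                     prob = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(letters, n, replace = TRUE, prob = prob), collapse = "")
}

rand_pwm <- function(width, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rgamma(4 * width, 1), 4, width)
  zfscreen::pwm(sweep(m, 2, colSums(m), "/"))
}

# exhaustive null: score every 4^W word with the same adjusted log-odds
# the scanner uses, accumulate background probabilities, and return the
# tail mass at a query score
brute_tail <- function(x, query_scores) {
  adj <- function(p) (p + x$pseudocount) / (1 + 4 * x$pseudocount)
  lo <- round(log2(adj(x$probs) / adj(x$background)), 9)
  sc <- 0
  wt <- 1
  for (j in seq_len(x$width)) {
    sc <- as.numeric(outer(lo[, j], sc, "+"))
    wt <- as.numeric(outer(adj(x$background), wt, "*"))
  }
  vapply(query_scores, function(s) sum(wt[sc >= s - 1e-9]), numeric(1))
}

# all-ATG walk ORF enumerator, independent of the frame-scan implementation
brute_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  atg <- gregexpr("ATG", s, fixed = TRUE)[[1]]
  if (atg[1] == -1L) return(NULL)
  for (a in as.integer(atg)) {
    pos <- a + 3L
    while (pos + 2L <= n) {
      cod <- substr(s, pos, pos + 2L)
      if (cod %in% stops) {
        len <- pos + 2L - a + 1L
        if (is.null(best) || len > best$length ||
            (len == best$length && a - 1L < best$start)) {
          best <- list(start = a - 1L, end = a - 1L + len, length = len)
        }
        break
      }
      pos <- pos + 3L
    }
  }
  best
}

# mean pairwise difference count per bp over all haplotype pairs
brute_pi <- function(m, window_length) {
  n <- nrow(m)
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(m[i, ] != m[j, ], na.rm = TRUE)
      np <- np + 1
    }
  }
  tot / np / window_length
}

# per-site Hudson sums written out longhand
brute_fst <- function(mA, mB) {
  hw <- hb <- numeric(0)
  for (k in seq_len(ncol(mA))) {
    a <- mA[, k][!is.na(mA[, k])]
    b <- mB[, k][!is.na(mB[, k])]
    pa <- mean(a); pb <- mean(b)
    na <- length(a); nb <- length(b)
    hwa <- 2 * pa * (1 - pa) * na / (na - 1)
    hwb <- 2 * pb * (1 - pb) * nb / (nb - 1)
    w <- (hwa + hwb) / 2
    btw <- pa * (1 - pb) + pb * (1 - pa)
    if (btw == 0 && w == 0) next
    hw <- c(hw, w); hb <- c(hb, btw)
  }
  if (length(hb) == 0 || mean(hb) == 0) return(NA_real_)
  1 - mean(hw) / mean(hb)
}

# random binary tree with positive branch lengths and its path-distance
# matrix (additive by construction)
rand_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 1))
  tr <- ape::unroot(tr)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

unrooted_splits <- function(tr) zfscreen:::tree_splits(tr)

# minimal diploid VCF writer for reader tests
write_test_vcf <- function(path, positions, gts, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(positions), function(i) {
    paste(c("chr9", positions[i], ".", "A", "G", ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# does the unrooted tree contain the bipartition separating `side`?
has_split <- function(tr, side) {
  tips <- sort(tr$tip.label)
  if (tips[1] %in% side) side <- setdiff(tips, side)
  paste(sort(side), collapse = "|") %in% unrooted_splits(tr)
}
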