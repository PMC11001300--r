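#' Pairwise distances from an aligned protein FASTA
#'
#' p-distance (mismatches / valid sites) with pairwise gap deletion:
#' alignment columns where either sequence of a pair has a gap (`-` or
#' `.`) or `X` are excluded for that pair only. The Poisson correction
#' `-ln(1 - p)` is applied by default.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, a `Biostrings::AAStringSet`, or a FASTA file path.
#' @param correction `"poisson"` (default) or `"none"`.
#' @return Symmetric distance matrix with taxa as dimnames.
#' @export
p_distance <- function(alignment, correction = c("poisson", "none")) {
  correction <- match.arg(correction)
  aln <- as_alignment(alignment)
  n <- length(aln)
  if (n < 2L) abort("need at least 2 sequences")
  L <- unique(nchar(aln))
  if (length(L) != 1L) abort("aligned sequences must all have equal length")
  chars <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
  valid <- !(chars %in% c("-", ".", "X"))
  dim(valid) <- dim(chars)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- valid[i, ] & valid[j, ]
      nv <- sum(both)
      if (nv == 0L) {
        abort(sprintf("no valid sites shared by %s and %s",
                      names(aln)[i], names(aln)[j]))
      }
      p <- sum(chars[i, both] != chars[j, both]) / nv
      d[i, j] <- d[j, i] <- if (correction == "poisson") {
        if (p >= 1) abort(sprintf(
          "saturated pair %s / %s: Poisson correction undefined",
          names(aln)[i], names(aln)[j])) else -log(1 - p)
      } else p
    }
  }
  d
}

as_alignment <- function(alignment) {
  if (inherits(alignment, "AAStringSet") ||
      inherits(alignment, "BStringSet")) {
    return(setNames(as.character(alignment), names(alignment)))
  }
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    x <- Biostrings::readAAStringSet(alignment)
    return(setNames(as.character(x), names(x)))
  }
  if (!is.character(alignment)) abort("unsupported alignment input")
  if (is.null(names(alignment))) {
    names(alignment) <- paste0("taxon", seq_along(alignment))
  }
  alignment
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: at each step the pair minimising
#' the Q criterion is joined; ties are broken by the smallest (i, j)
#' index pair in the current taxon ordering. Limb lengths come from the
#' standard formulas; a negative limb is clamped to 0 and its deficit
#' transferred to the sibling limb so path lengths through the new node
#' are preserved.
#'
#' @param d Symmetric distance matrix with >= 3 taxa (dimnames used as
#'   tip labels).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) abort("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  }
  labels <- rownames(d)
  # each active node is carried as a newick fragment (no trailing ;)
  frags <- as.list(labels)
  while (length(frags) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]
    j <- cand[1, 2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    cl <- clamp_limbs(li, lj)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frags[[i]], cl[1],
                        frags[[j]], cl[2])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    du <- du[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    frags <- c(frags[-c(i, j)], list(new_frag))
    rownames(d) <- colnames(d) <- NULL
  }
  # resolve the final three around a single internal node
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", frags[[1]], la,
                 frags[[2]], lb, frags[[3]], lc)
  ape::read.tree(text = nwk)
}

# clamp negative limb to 0, moving the deficit to the sibling
clamp_limbs <- function(li, lj) {
  if (li < 0) { lj <- lj + li; li <- 0 }
  if (lj < 0) { li <- li + lj; lj <- 0 }
  c(max(li, 0), max(lj, 0))
}

# canonical bipartition keys of the internal edges of an unrooted tree
tree_splits <- function(tr) {
  tips <- sort(tr$tip.label)
  ntip <- length(tr$tip.label)
  anchor <- tips[1]
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    child <- tr$edge[e, 2]
    if (child <= ntip) next
    below <- ape::extract.clade(tr, child)$tip.label
    if (anchor %in% below) below <- setdiff(tips, below)
    if (length(below) < 2L || length(below) > ntip - 2L) next
    keys <- c(keys, paste(sort(below), collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_reps` times; the support of each internal edge is the
#' percentage of replicate trees containing the same bipartition.
#' Replicate r draws its resampling from a deterministic substream
#' seeded with `seed + r`, so results are reproducible.
#'
#' @inheritParams p_distance
#' @param n_reps Number of bootstrap replicates (default 2000).
#' @param seed Integer seed governing all replicates.
#' @return The full-data `ape::phylo` tree with `node.label` holding
#'   integer support percentages on internal nodes (root label empty).
#' @export
bootstrap_support <- function(alignment, n_reps = 2000, seed = 1,
                              correction = c("poisson", "none")) {
  correction <- match.arg(correction)
  aln <- as_alignment(alignment)
  aln <- aln[order(names(aln))]  # support invariant to input order
  if (n_reps < 1) abort("n_reps must be >= 1")
  main <- neighbor_joining(p_distance(aln, correction))
  L <- nchar(aln[[1]])
  splits_main <- tree_splits(main)
  counts <- setNames(numeric(length(splits_main)), splits_main)
  chars <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  for (rep in seq_len(n_reps)) {
    set.seed(seed + rep)
    cols <- sample.int(L, L, replace = TRUE)
    res <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
    names(res) <- names(aln)
    tr <- neighbor_joining(p_distance(res, correction))
    sp <- tree_splits(tr)
    hit <- splits_main %in% sp
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_reps)
  # attach supports as node labels
  ntip <- length(main$tip.label)
  nlab <- character(main$Nnode)
  for (node in seq_len(main$Nnode) + ntip) {
    below <- ape::extract.clade(main, node)$tip.label
    tips <- sort(main$tip.label)
    if (tips[1] %in% below) below <- setdiff(tips, below)
    if (length(below) < 2L || length(below) > ntip - 2L) {
      nlab[node - ntip] <- ""
      next
    }
    key <- paste(sort(below), collapse = "|")
    nlab[node - ntip] <- if (key %in% names(support)) {
      as.character(support[[key]])
    } else ""
  }
  main$node.label <- nlab
  main
}

#' Write a tree with branch lengths and support values as Newick
#'
#' @param tree An `ape::phylo`, e.g. from [bootstrap_support()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
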