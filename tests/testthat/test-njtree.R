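test_that("p-distances follow hand counts with pairwise gap deletion", {
  aln <- c(a = "AAAA", b = "AAAT")
  expect_equal(unname(p_distance(aln, "none")["a", "b"]), 0.25)
  expect_equal(unname(p_distance(c(a = "MKV", b = "MKV"), "none")["a", "b"]),
               0)
  gap <- c(a = "AA-A", b = "AATA")
  expect_equal(unname(p_distance(gap, "none")["a", "b"]), 0)
  expect_equal(unname(p_distance(aln, "poisson")["a", "b"]), -log(0.75))
  expect_error(p_distance(c(a = "--A", b = "A--"), "none"), "valid sites")
  expect_error(p_distance(c(a = "AA", b = "AAA")), "equal length")
})

test_that("NJ recovers a 4-taxon additive tree with exact path lengths", {
  d <- matrix(c(0, 2, 4, 6,
                2, 0, 4, 6,
                4, 4, 0, 4,
                6, 6, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_s3_class(tr, "phylo")
  co <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(co, d, tolerance = 1e-9)
  expect_true(has_split(tr, c("A", "B")))
  expect_equal(length(unrooted_splits(tr)), 1L)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
})

test_that("three taxa resolve by the three-point formulas", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len["x"]), 1)
  expect_equal(unname(len["y"]), 2)
  expect_equal(unname(len["z"]), 4)
})

test_that("NJ topology is invariant to taxon input order", {
  ref <- rand_additive(7, seed = 61)
  t1 <- neighbor_joining(ref$d)
  perm <- sample(7)
  t2 <- neighbor_joining(ref$d[perm, perm])
  expect_setequal(unrooted_splits(t1), unrooted_splits(t2))
})

test_that("NJ is exact on random additive matrices", {
  for (seed in 1:30) {
    ref <- rand_additive(sample(5:9, 1), seed = 700 + seed)
    tr <- neighbor_joining(ref$d)
    expect_setequal(unrooted_splits(tr), unrooted_splits(ref$tree))
    co <- ape::cophenetic.phylo(tr)[rownames(ref$d), colnames(ref$d)]
    expect_equal(co, ref$d, tolerance = 1e-8)
  }
})

test_that("NJ topologies agree with an independent implementation on
          noisy matrices", {
  for (seed in 1:10) {
    ref <- rand_additive(6, seed = 800 + seed)
    set.seed(seed)
    noisy <- ref$d + matrix(runif(36, 0, 0.02), 6, 6)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    expect_setequal(unrooted_splits(neighbor_joining(noisy)),
                    unrooted_splits(ape::nj(noisy)))
  }
})

test_that("branch lengths are never negative after clamping", {
  # strongly non-additive matrix prone to negative limbs
  set.seed(9)
  d <- matrix(runif(36, 0.1, 1), 6, 6)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap support behaves at the invariant limits and is
          seed-deterministic", {
  core <- "GGGGPPPPSSSS"
  aln <- c(t1 = paste0("MKVLLLAAAAWWW", core),
           t2 = paste0("MKVLLLAAAAWWW", core),
           t3 = paste0("QQQYYYCCCHHHH", core),
           t4 = paste0("NNNFFFGGGIIII", core),
           t5 = paste0("DDDEEERRRKKKK", core))
  bt <- bootstrap_support(aln, n_reps = 50, seed = 4)
  expect_true(has_split(bt, c("t1", "t2")))
  lab <- bt$node.label[bt$node.label != ""]
  key_support <- NULL
  ntip <- 5
  for (node in seq_len(bt$Nnode) + ntip) {
    below <- ape::extract.clade(bt, node)$tip.label
    if (setequal(below, c("t1", "t2"))) {
      key_support <- bt$node.label[node - ntip]
    }
  }
  expect_equal(key_support, "100")

  one <- bootstrap_support(aln, n_reps = 1, seed = 9)
  sup <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))

  b1 <- bootstrap_support(aln, n_reps = 30, seed = 123)
  b2 <- bootstrap_support(aln, n_reps = 30, seed = 123)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  # input order does not change supports
  b3 <- bootstrap_support(aln[c(3, 1, 5, 2, 4)], n_reps = 30, seed = 123)
  expect_identical(sort(b1$node.label), sort(b3$node.label))
})

test_that("trees round-trip through Newick", {
  ref <- rand_additive(5, seed = 77)
  tr <- neighbor_joining(ref$d)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(unrooted_splits(back), unrooted_splits(tr))
})
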