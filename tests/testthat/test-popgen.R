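test_that("pi matches hand cases and the pairwise oracle", {
  # 2 haplotypes differing at 1 of 100 bp
  m <- rbind(rep(0L, 3), c(1L, 0L, 0L))
  expect_equal(nucleotide_diversity(m, 100), 0.01)
  expect_equal(nucleotide_diversity(rbind(0L, 0L), 100), 0)
  for (seed in 1:20) {
    set.seed(200 + seed)
    mm <- matrix(rbinom(10 * 12, 1, runif(1, 0.1, 0.9)), nrow = 10)
    expect_equal(nucleotide_diversity(mm, 500), brute_pi(mm, 500),
                 tolerance = 1e-12)
  }
  expect_error(nucleotide_diversity(m, 0), "positive")
})

test_that("Hudson's Fst matches limits and the per-site oracle", {
  expect_equal(hudson_fst(matrix(0L, 5, 1), matrix(1L, 7, 1)), 1)
  set.seed(41)
  # two independent large samples from identical true frequencies
  p <- runif(30, 0.2, 0.8)
  mkpop <- function(n) matrix(rbinom(n * 30, 1, rep(p, each = n)), nrow = n)
  f0 <- hudson_fst(mkpop(300), mkpop(300))
  expect_lt(abs(f0), 0.02)
  for (seed in 1:20) {
    set.seed(300 + seed)
    mA <- matrix(rbinom(8 * 5, 1, runif(5, .1, .9)), nrow = 8, byrow = TRUE)
    mB <- matrix(rbinom(10 * 5, 1, runif(5, .1, .9)), nrow = 10, byrow = TRUE)
    expect_equal(hudson_fst(mA, mB), brute_fst(mA, mB), tolerance = 1e-12)
    expect_equal(hudson_fst(mA, mB), hudson_fst(mB, mA), tolerance = 1e-12)
  }
  # monomorphic-everywhere window is undefined
  expect_true(is.na(hudson_fst(matrix(0L, 4, 2), matrix(0L, 4, 2))))
})

test_that("pi is invariant to relabeling haplotypes within a population", {
  set.seed(77)
  m <- matrix(rbinom(60, 1, 0.3), nrow = 10)
  expect_equal(nucleotide_diversity(m, 100),
               nucleotide_diversity(m[sample(10), ], 100))
})

test_that("windows tile the region and empty windows are distinct from
          monomorphic ones", {
  pos <- c(500, 1500, 7200)
  alle <- matrix(c(0L, 1L), nrow = 6, ncol = 3)
  alle[, 3] <- 0L  # monomorphic site
  hm <- haplotype_matrix(alle, pos, pops = rep(c("A", "B"), each = 3))
  st <- sliding_windows(hm, region = c(0, 10000), window = 5000,
                        step = 1000)
  expect_equal(nrow(st), 6L)
  expect_equal(st$start, seq(0, 5000, 1000))
  # window [3000,8000) holds only the monomorphic site: pi defined, 0
  w <- st[st$start == 3000, ]
  expect_equal(w$n_sites, 1L)
  expect_equal(w$pi_A, 0)
  # [6000,10000)? last window start 5000 covers site 7200
  expect_warning(
    empty <- sliding_windows(hm, region = c(20000, 30000)), "outside")
  expect_equal(nrow(empty), 0L)
})

test_that("the empirical top-quantile rule flags the expected windows", {
  st <- tibble::tibble(seq_id = "c", start = 0:99, end = 1:100,
                       n_sites = 1L, pi_A = 1, pi_B = 1,
                       fst = as.numeric(1:100))
  thr <- top_quantile_threshold(st, "fst", 0.95)
  expect_equal(thr, unname(quantile(1:100, 0.95)))
  expect_gt(thr, 95); expect_lt(thr, 96)
  fl <- flag_outlier_windows(st, "fst", 0.95)
  expect_equal(fl$start[fl$outlier], 95:99)  # values 96..100
  cst <- dplyr::mutate(st, fst = 0.5)
  expect_equal(top_quantile_threshold(cst, "fst"), 0.5)
  expect_true(all(flag_outlier_windows(cst, "fst")$outlier))
  one <- st[1, ]
  expect_equal(top_quantile_threshold(one, "fst"), 1)
  expect_error(top_quantile_threshold(st, "fst", 1.2), "q must")
})

test_that("VCF and matrix TSV readers give the same haplotypes", {
  gts <- rbind(c("0/0", "0/1", "1/1"),
               c("0/1", "./.", "0/0"),
               c("1|1", "0|0", "0|1"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(f, c(101, 205, 900), gts, c("s1", "s2", "s3"))
  pf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("s1\twild", "s2\twild", "s3\tdomestic"), pf)
  hm <- read_haplotypes_vcf(f, pf)
  expect_equal(hm$positions, c(100, 204, 899))
  expect_equal(dim(hm$alleles), c(6L, 3L))
  expect_equal(sort(unique(hm$pops)), c("domestic", "wild"))
  # s2 second site missing on both haplotypes
  s2 <- hm$alleles[grepl("^s2", hm$sample_ids), 2]
  expect_true(all(is.na(s2)))
  # frequency of alt at site 1: s1 0/0, s2 0/1, s3 1/1 -> 3/6
  expect_equal(mean(hm$alleles[, 1], na.rm = TRUE), 0.5)

  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample = hm$sample_ids, pop = hm$pops,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(hm$alleles))
  colnames(df)[3:5] <- hm$positions
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  hm2 <- read_haplotypes_tsv(tf)
  expect_equal(unname(hm2$alleles), unname(hm$alleles))
  expect_equal(hm2$positions, hm$positions)
})

test_that("multi-allelic sites are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2")
  body <- c("chr9\t10\t.\tA\tG\t.\t.\t.\tGT\t0/1\t0/0",
            "chr9\t20\t.\tA\tG,C\t.\t.\t.\tGT\t0/2\t0/0")
  writeLines(c(hdr, body), f)
  pf <- withr::local_tempfile()
  writeLines(c("s1\tA", "s2\tB"), pf)
  expect_warning(hm <- read_haplotypes_vcf(f, pf), "multi-allelic")
  expect_equal(length(hm$positions), 1L)
})

test_that("window-stat plotting returns a ggplot", {
  hm <- simulate_haplotypes(n_a = 12, n_b = 15, region_length = 30000,
                            diverged_window = c(10000, 15000), seed = 2)
  st <- sliding_windows(hm, window = 5000, step = 2500)
  expect_s3_class(plot_window_stats(st), "ggplot")
})
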