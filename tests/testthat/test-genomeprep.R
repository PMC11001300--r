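gff_lines <- function(...) c("##gff-version 3", ...)

test_that("GFF3 gene records convert to 0-based half-open coordinates", {
  g <- read_gene_models(gff_lines(
    "chr1\t.\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\t.\tmRNA\t1001\t2000\t.\t+\t.\tID=t1"))
  expect_equal(g$start, 1000L)
  expect_equal(g$end, 2000L)
  expect_equal(g$gene_id, "gA")
  expect_equal(nrow(read_gene_models(gff_lines())), 0L)
})

test_that("gene models come back sorted and malformed records are
          skipped with line numbers", {
  g <- read_gene_models(gff_lines(
    "chr1\t.\tgene\t5001\t6000\t.\t-\t.\tID=g2",
    "chr1\t.\tgene\t1001\t2000\t.\t+\t.\tID=g1"))
  expect_equal(g$gene_id, c("g1", "g2"))
  expect_warning(
    bad <- read_gene_models(gff_lines(
      "chr1\t.\tgene\t900\t100\t.\t+\t.\tID=bad1",
      "chr1\t.\tgene\t1\t10\t.\t+\t.\tID=ok")),
    "line 2")
  expect_equal(bad$gene_id, "ok")
  expect_warning(
    read_gene_models(gff_lines("chr1\t.\tgene\t1\t10\t.\t?\t.\tID=x")),
    "strand")
})

test_that("flanks obey strand-aware arithmetic and edge clipping", {
  genome <- c(chr1 = rand_dna(10000, seed = 5))
  plus <- tibble::tibble(gene_id = "gp", seq_id = "chr1", start = 5000L,
                         end = 6000L, strand = "+")
  fl <- extract_flanks(genome, plus, flank = 2000)
  up <- fl[fl$kind == "upstream", ]
  dn <- fl[fl$kind == "downstream", ]
  expect_equal(c(up$start, up$end), c(3000, 5000))
  expect_equal(c(dn$start, dn$end), c(6000, 8000))
  expect_false(any(fl$truncated))
  expect_equal(up$sequence, unname(toupper(substr(genome, 3001, 5000))))

  minus <- tibble::tibble(gene_id = "gm", seq_id = "chr1", start = 5000L,
                          end = 6000L, strand = "-")
  flm <- extract_flanks(genome, minus, flank = 2000)
  upm <- flm[flm$kind == "upstream", ]
  expect_equal(c(upm$start, upm$end), c(6000, 8000))
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(
    substr(genome, 6001, 8000), "")[[1]]), collapse = ""))
  expect_equal(upm$sequence, rc)

  edge <- tibble::tibble(gene_id = "ge", seq_id = "chr1", start = 500L,
                         end = 900L, strand = "+")
  fe <- extract_flanks(genome, edge, flank = 2000)
  ue <- fe[fe$kind == "upstream", ]
  expect_equal(c(ue$start, ue$end), c(0, 500))
  expect_true(ue$truncated)

  expect_error(extract_flanks(genome, dplyr::mutate(plus, seq_id = "nope")),
               "missing.*gp")
})

test_that("flanks never overlap the gene body", {
  genome <- c(c1 = rand_dna(50000, seed = 6))
  set.seed(7)
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:8), seq_id = "c1",
    start = as.integer(seq(3000, 45000, length.out = 8)),
    end = as.integer(seq(3000, 45000, length.out = 8) + 800),
    strand = sample(c("+", "-"), 8, TRUE))
  fl <- extract_flanks(genome, genes, flank = 1500)
  joined <- dplyr::inner_join(fl, genes, by = "gene_id",
                              suffix = c("", ".g"))
  expect_true(all(joined$end <= joined$start.g | joined$start >= joined$end.g))
})

test_that("scanning flanks agrees with scanning the genome and filtering
          to flank intervals (+ strand genes)", {
  x <- mamo_pwm()
  sim <- simulate_genome(n_genes = 6, contig_length = 60000,
                         n_true_targets = 4, seed = 13)
  genes <- sim$genes[sim$genes$strand == "+", ]
  fl <- extract_flanks(sim$genome, genes)
  hits_fl <- scan_flanks(fl, x, background = rep(0.25, 4))
  hits_gen <- scan_pwm(sim$genome, x, background = rep(0.25, 4))
  in_flank <- dplyr::cross_join(hits_gen, fl) |>
    dplyr::filter(.data$start.x >= .data$start.y,
                  .data$start.x + 9 <= .data$end)
  expect_equal(nrow(hits_fl), nrow(in_flank))
  genomic_from_flank <- dplyr::inner_join(
    hits_fl, fl, by = c("gene_id", "kind"), suffix = c("", ".f")) |>
    dplyr::mutate(gstart = ifelse(.data$strand.f == "+",
                                  .data$start.f + .data$start,
                                  .data$end.f - .data$start - 9))
  expect_setequal(genomic_from_flank$gstart, in_flank$start.x)
})

test_that("longest ORF matches hand cases and the exhaustive enumerator", {
  expect_equal(longest_orf("ATGAAATAA")$length, 9L)
  two <- "CCATGTGATAAATGAAAAAATAG"
  expect_equal(longest_orf(two)$length, brute_orf(two)$length)
  expect_equal(longest_orf(two)$start, brute_orf(two)$start)
  expect_equal(nrow(longest_orf("CCCCCC")), 0L)
  expect_error(longest_orf("ATGQ"), "non-DNA")
  for (seed in 1:60) {
    s <- rand_dna(300, seed = 4000 + seed)
    got <- longest_orf(s)
    want <- brute_orf(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$length, want$length)
      expect_equal(got$start, want$start)
    }
  }
})
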