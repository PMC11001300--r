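test_that("a single embedded C2H2 finger is detected with correct helix", {
  prot <- paste0(strrep("A", 10), ZIF_FINGER)
  f <- find_zf_domains(prot)
  expect_equal(nrow(f), 1L)
  # second C at protein position 15 (0-based), helix = linker + 1 onward
  expect_equal(f$helix_residues[[1]],
               c("-1" = "R", "1" = "S", "2" = "D", "3" = "H",
                 "4" = "L", "5" = "T", "6" = "T"))
  expect_equal(substr(prot, f$start[1] + 1, f$end[1]), f$sequence[1])
})

test_that("proteins without the C2H2 pattern give an empty table", {
  expect_equal(nrow(find_zf_domains("MKKKKKK")), 0L)
  expect_error(find_zf_domains(""), "non-empty")
  expect_error(find_zf_domains("MK3X"), "non-letter")
})

test_that("concatenated proteins yield the union of their fingers", {
  p1 <- paste0("MAA", ZIF_FINGER, "GS")
  p2 <- paste0("MTT", ZIF_FINGER, ZIF_FINGER)
  f1 <- find_zf_domains(p1)
  f2 <- find_zf_domains(p2)
  fcat <- find_zf_domains(paste0(p1, strrep("X", 30), p2))
  expect_equal(nrow(fcat), nrow(f1) + nrow(f2))
  # spans never overlap
  expect_true(all(fcat$start[-1] >= fcat$end[-nrow(fcat)]))
})

test_that("the canonical code maps residues -1/3/6 onto the triplet", {
  code <- tibble::tibble(
    position = c("6", "3", "-1"), residue = c("R", "E", "R"),
    pA = 0, pC = c(0, 1, 0), pG = c(1, 0, 1), pT = 0)
  fing <- tibble::tibble(
    index = 1L, start = 0L, end = 24L, sequence = "f", confidence = 1,
    helix_residues = list(c("-1" = "R", "1" = "S", "2" = "D", "3" = "E",
                            "4" = "L", "5" = "T", "6" = "R")))
  p1 <- predict_pwm(fing, code)
  expect_equal(consensus(p1), "GCG")
  p2 <- predict_pwm(dplyr::bind_rows(fing, fing), code)
  expect_equal(consensus(p2), "GCGGCG")
})

test_that("fingers are arrayed antiparallel: reversing the array reverses
          the motif triplet-blockwise", {
  code <- default_recognition_code()
  f2 <- tibble::tibble(
    index = 1:2, start = c(0L, 30L), end = c(24L, 54L),
    sequence = c("a", "b"), confidence = 1,
    helix_residues = list(
      c("-1" = "R", "1" = "S", "2" = "D", "3" = "E", "4" = "L",
        "5" = "T", "6" = "R"),
      c("-1" = "Q", "1" = "S", "2" = "S", "3" = "H", "4" = "L",
        "5" = "T", "6" = "T")))
  fwd <- consensus(predict_pwm(f2, code))
  rev_ <- consensus(predict_pwm(f2[2:1, ], code))
  blocks <- function(s) substring(s, c(1, 4), c(3, 6))
  expect_equal(blocks(rev_), rev(blocks(fwd)))
})

test_that("uniform or missing code entries give uniform columns", {
  fing <- find_zf_domains(paste0("M", ZIF_FINGER))
  ucode <- default_recognition_code()
  ucode[, c("pA", "pC", "pG", "pT")] <- 0.25
  pu <- predict_pwm(fing, ucode)
  expect_true(all(apply(pu$probs, 2, function(x) diff(range(x))) == 0))
  # drop exactly one entry the fixture needs: (3, H)
  small <- dplyr::filter(default_recognition_code(),
                         !(position == "3" & residue == "H"))
  expect_warning(pm <- predict_pwm(fing, small), "position 3 residue H")
  expect_true(all(abs(colSums(pm$probs) - 1) < 1e-9))
  expect_error(predict_pwm(fing[0, ], ucode), "non-empty")
})

test_that("the optional cross-strand position-2 column complements its
          preference vector", {
  code <- tibble::tibble(
    position = c("6", "3", "-1", "2"), residue = c("R", "E", "R", "D"),
    pA = c(0, 0, 0, 1), pC = c(0, 1, 0, 0), pG = c(1, 0, 1, 0), pT = 0)
  fing <- tibble::tibble(
    index = 1L, start = 0L, end = 24L, sequence = "f", confidence = 1,
    helix_residues = list(c("-1" = "R", "1" = "S", "2" = "D", "3" = "E",
                            "4" = "L", "5" = "T", "6" = "R")))
  p4 <- predict_pwm(fing, code, cross_strand_pos2 = TRUE)
  expect_equal(p4$width, 4L)
  # (2, D) prefers A on the complementary strand -> T on the sense strand
  expect_equal(consensus(p4), "GCGT")
})

test_that("recognition-code tables round-trip and are validated", {
  code <- default_recognition_code()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recognition_code(code, f)
  expect_equal(read_recognition_code(f), code, ignore_attr = TRUE)
  bad <- code
  bad$pA[1] <- 2
  expect_error(write_recognition_code(bad, f), "probability")
  shipped <- read_recognition_code(system.file(
    "extdata", "recognition_code.tsv", package = "zfscreen"))
  expect_true(all(abs(rowSums(shipped[, c("pA", "pC", "pG", "pT")]) - 1)
                  < 1e-9))
})
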