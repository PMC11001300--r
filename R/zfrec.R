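#' Detect C2H2 zinc-finger domains in a protein sequence
#'
#' Finds non-overlapping matches to the classical Cys2His2 spacing
#' pattern `C-x(1,4)-C-x(12)-H-x(3,5)-H` and extracts the alpha-helix
#' recognition residues. Helix position 1 is the first residue of the
#' recognition helix, located 7 residues after the second coordinating
#' cysteine (i.e. one residue past the 6-residue linker that follows it);
#' position -1 is the residue immediately N-terminal to position 1, and
#' position 6 is the residue immediately before the first coordinating
#' histidine. With that numbering the Zif268 finger-1 fixture
#' `FQCRICMRNFSRSDHLTTHIRTHT` yields helix residues -1=R, 1=S, 2=D, 3=H,
#' 4=L, 5=T, 6=T.
#'
#' The confidence score is a simple structural-feature count in 1..3
#' (base 1 for the pattern match, +1 for the canonical CXXC spacing, +1
#' for a hydrophobic residue at helix position 4); it is not comparable
#' to external prediction-server scores.
#'
#' @param protein Amino-acid sequence (single string, 20-letter alphabet,
#'   X allowed outside the coordinating C/H residues).
#' @param min_confidence Keep fingers with confidence >= this (default 0,
#'   i.e. all pattern matches).
#' @return Tibble with one row per finger, N-terminal to C-terminal:
#'   `index`, `start`, `end` (0-based half-open protein coordinates),
#'   `sequence`, `confidence`, and a list-column `helix_residues`
#'   (named character vector for positions -1, 1, 2, 3, 4, 5, 6).
#'   No match gives a 0-row tibble; empty input is an error.
#' @examples
#' find_zf_domains(paste0(strrep("A", 10), "FQCRICMRNFSRSDHLTTHIRTHT"))
#' @export
find_zf_domains <- function(protein, min_confidence = 0) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein)) {
    abort("protein must be a single non-empty string")
  }
  protein <- toupper(protein)
  if (grepl("[^A-Z]", protein)) abort("protein contains non-letter characters")
  pat <- "C[A-Z]{1,4}?C[A-Z]{12}H[A-Z]{3,5}?H"
  m <- gregexpr(pat, protein, perl = TRUE)[[1]]
  empty <- tibble(index = integer(), start = integer(), end = integer(),
                  sequence = character(), confidence = numeric(),
                  helix_residues = list())
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  rows <- purrr::map2(starts, lens, function(s, l) {
    seq <- substr(protein, s, s + l - 1L)
    # re-match with capture groups to locate the second coordinating C
    g <- regexec("^(C)([A-Z]{1,4}?)(C)([A-Z]{12})(H)([A-Z]{3,5}?)(H)$",
                 seq, perl = TRUE)[[1]]
    parts <- regmatches(seq, list(g))[[1]]
    x1_len <- nchar(parts[3])
    c2 <- 2L + x1_len            # 1-based position of second C in seq
    hel_idx <- c2 + c(6L, 7L, 8L, 9L, 10L, 11L, 12L)
    hel <- substring(seq, hel_idx, hel_idx)
    names(hel) <- c("-1", "1", "2", "3", "4", "5", "6")
    conf <- 1 + (x1_len == 2L) + (hel[["4"]] %in%
                                    c("L", "I", "V", "M", "F", "Y"))
    list(start = s - 1L, end = s - 1L + l, sequence = seq,
         confidence = as.numeric(conf), helix = hel)
  })
  out <- tibble(
    index = seq_along(rows),
    start = purrr::map_int(rows, "start"),
    end = purrr::map_int(rows, "end"),
    sequence = purrr::map_chr(rows, "sequence"),
    confidence = purrr::map_dbl(rows, "confidence"),
    helix_residues = purrr::map(rows, "helix")
  )
  out <- dplyr::filter(out, .data$confidence >= .env$min_confidence)
  out$index <- seq_len(nrow(out))
  out
}

#' Default C2H2 recognition-code table
#'
#' A compact lookup table mapping (helix position, amino acid) to a base
#' preference distribution under the canonical binding model, distilled
#' from classical C2H2 recognition studies (e.g. arginine at positions
#' -1/6 prefers G, glutamate/aspartate at position 3 prefer C). Residues
#' absent from the table fall back to the uniform distribution. The table
#' is deliberately coarse and fully user-replaceable via
#' [read_recognition_code()].
#'
#' @param main_prob Probability assigned to the preferred base of each
#'   entry (default 0.85); the remainder is split over the other bases.
#' @return Tibble with columns `position`, `residue`, `pA`, `pC`, `pG`,
#'   `pT`.
#' @export
default_recognition_code <- function(main_prob = 0.85) {
  prefs <- tibble::tribble(
    ~position, ~residue, ~base,
    "-1", "R", "G",  "-1", "K", "T",  "-1", "Q", "A",  "-1", "N", "A",
    "-1", "D", "C",  "-1", "E", "C",  "-1", "T", "A",  "-1", "H", "G",
    "2",  "D", "C",  "2",  "E", "C",  "2",  "S", "A",  "2",  "T", "A",
    "2",  "R", "G",  "2",  "K", "G",
    "3",  "E", "C",  "3",  "D", "C",  "3",  "H", "G",  "3",  "N", "A",
    "3",  "T", "T",  "3",  "S", "T",  "3",  "K", "G",  "3",  "R", "G",
    "6",  "R", "G",  "6",  "K", "G",  "6",  "Q", "A",  "6",  "E", "C",
    "6",  "T", "T",  "6",  "H", "G",  "6",  "N", "A",  "6",  "D", "C",
    "6",  "S", "T",  "6",  "V", "A"
  )
  rest <- (1 - main_prob) / 3
  m <- matrix(rest, nrow = nrow(prefs), ncol = 4,
              dimnames = list(NULL, paste0("p", DNA_BASES)))
  m[cbind(seq_len(nrow(prefs)), match(prefs$base, DNA_BASES))] <- main_prob
  dplyr::bind_cols(prefs[, c("position", "residue")], as_tibble(m))
}

#' Read / write a recognition-code table
#'
#' TSV with columns `position` (helix position label), `residue` (one
#' amino-acid letter), `pA`, `pC`, `pG`, `pT`. Every row's probabilities
#' must be non-negative and sum to 1 (tolerance 1e-9).
#'
#' @param path TSV path.
#' @return Tibble in the same layout as [default_recognition_code()].
#' @export
read_recognition_code <- function(path) {
  df <- as_tibble(read.delim(path, comment.char = "#", colClasses = c(
    position = "character", residue = "character")))
  validate_recognition_code(df)
  df
}

#' @rdname read_recognition_code
#' @param code Recognition-code tibble.
#' @export
write_recognition_code <- function(code, path) {
  validate_recognition_code(code)
  write.table(code, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_recognition_code <- function(code) {
  need <- c("position", "residue", paste0("p", DNA_BASES))
  if (!all(need %in% names(code))) {
    abort(paste("recognition code must have columns:",
                paste(need, collapse = ", ")))
  }
  m <- as.matrix(code[, paste0("p", DNA_BASES)])
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
    abort("every recognition-code row must be a probability vector")
  }
  invisible(code)
}

code_lookup <- function(code, position, residue) {
  row <- which(code$position == position & code$residue == residue)
  if (length(row) == 0L) {
    warn(sprintf(
      "no recognition-code entry for position %s residue %s; using uniform",
      position, residue))
    return(rep(0.25, 4))
  }
  as.numeric(code[row[1], paste0("p", DNA_BASES)])
}

#' Predict a DNA-binding PWM from a zinc-finger array
#'
#' Applies the canonical binding model: each finger reads a 3-bp
#' sense-strand triplet with helix residue 6 specifying base 1, residue 3
#' base 2, and residue -1 base 3; fingers are arrayed antiparallel to the
#' DNA, so the C-terminal finger's triplet occupies the 5' end of the
#' motif. Optionally, the residue at helix position 2 (which contacts the
#' complementary strand of the base 3'-adjacent to the triplet) adds a
#' fourth column per finger, entered on the sense strand as the
#' complement of its preference vector.
#'
#' @param fingers Tibble from [find_zf_domains()] with >= 1 row.
#' @param code Recognition-code tibble (default
#'   [default_recognition_code()]). Missing (position, residue) entries
#'   fall back to uniform with a warning.
#' @param cross_strand_pos2 Add the position-2 cross-strand column per
#'   finger (default FALSE, giving 3 bp per finger).
#' @param id Motif id for the returned PWM.
#' @inheritParams pwm
#' @return A `zf_pwm` of width `3 * n_fingers` (or `4 * n_fingers` with
#'   `cross_strand_pos2`).
#' @export
predict_pwm <- function(fingers, code = default_recognition_code(),
                        cross_strand_pos2 = FALSE, id = "predicted",
                        background = rep(0.25, 4), pseudocount = 0.25) {
  if (!is.data.frame(fingers) || nrow(fingers) == 0L) {
    abort("fingers must be a non-empty zinc-finger table")
  }
  validate_recognition_code(code)
  cols <- list()
  # antiparallel: C-terminal finger first (5' end of the motif)
  for (i in rev(seq_len(nrow(fingers)))) {
    hel <- fingers$helix_residues[[i]]
    cols <- c(cols, list(code_lookup(code, "6", hel[["6"]]),
                         code_lookup(code, "3", hel[["3"]]),
                         code_lookup(code, "-1", hel[["-1"]])))
    if (cross_strand_pos2) {
      cols <- c(cols, list(code_lookup(code, "2", hel[["2"]])[COMP_IDX]))
    }
  }
  pwm(do.call(cbind, cols), id = id, background = background,
      pseudocount = pseudocount)
}
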