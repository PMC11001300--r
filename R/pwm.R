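#' Construct a position weight matrix object
#'
#' A `zf_pwm` bundles a 4 x W base-probability matrix with the background
#' model and pseudocount used when it is turned into log-odds scores.
#'
#' @param probs Numeric 4 x W matrix; rows are A, C, G, T in that order
#'   (row names, if present, must be a permutation of A, C, G, T and are
#'   used to reorder). Every column must sum to 1 (tolerance 1e-9).
#' @param id Motif identifier.
#' @param background Length-4 base frequency vector (A, C, G, T), summing
#'   to 1. Default uniform.
#' @param pseudocount Non-negative pseudocount added to each probability
#'   (and to the background) before log-odds scoring; both are rescaled to
#'   sum to 1 again. Default 0.25.
#' @return An object of class `zf_pwm`.
#' @export
pwm <- function(probs, id = "motif", background = rep(0.25, 4),
                pseudocount = 0.25) {
  probs <- as.matrix(probs)
  if (!is.null(rownames(probs))) {
    if (!setequal(rownames(probs), DNA_BASES)) {
      abort("probs row names must be A, C, G, T")
    }
    probs <- probs[DNA_BASES, , drop = FALSE]
  }
  if (nrow(probs) != 4L) abort("probs must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 1L) abort("PWM width must be >= 1")
  if (any(probs < 0)) abort("PWM probabilities must be non-negative")
  csums <- colSums(probs)
  if (any(abs(csums - 1) > 1e-9)) abort("every PWM column must sum to 1")
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9) {
    abort("background must be 4 non-negative frequencies summing to 1")
  }
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  rownames(probs) <- DNA_BASES
  colnames(probs) <- NULL
  structure(
    list(id = id, width = ncol(probs), probs = probs,
         background = setNames(as.numeric(background), DNA_BASES),
         pseudocount = pseudocount),
    class = "zf_pwm"
  )
}

#' Build a PWM from a consensus sequence
#'
#' Each column assigns `match_prob` to the consensus base and splits the
#' remainder equally over the other three bases.
#'
#' @param consensus DNA string over A, C, G, T (ambiguity codes rejected).
#' @param match_prob Probability of the consensus base per column; must
#'   exceed 1/4 so the consensus is recoverable.
#' @inheritParams pwm
#' @return A `zf_pwm` of width `nchar(consensus)`.
#' @examples
#' pwm_from_consensus("GTGCGTGGC", 0.97)
#' @export
pwm_from_consensus <- function(consensus, match_prob = 0.97,
                               id = consensus, background = rep(0.25, 4),
                               pseudocount = 0.25) {
  if (!is.character(consensus) || length(consensus) != 1L ||
      nchar(consensus) < 1L) {
    abort("consensus must be a single non-empty string")
  }
  letters <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  idx <- match(letters, DNA_BASES)
  if (anyNA(idx)) abort("consensus must contain only A, C, G, T")
  if (match_prob <= 0.25 || match_prob > 1) {
    abort("match_prob must lie in (0.25, 1]")
  }
  m <- matrix((1 - match_prob) / 3, nrow = 4, ncol = length(idx))
  m[cbind(idx, seq_along(idx))] <- match_prob
  pwm(m, id = id, background = background, pseudocount = pseudocount)
}

#' The packaged Bm-mamo-S binding-site motif
#'
#' A width-9 PWM built from the printed consensus of the predicted
#' Bm-mamo-S binding site, GTGCGTGGC, which carries the EMSA-validated
#' mamo core TGCGT. Shipped so downstream stages (flank scanning, target
#' nomination) have a fixed, code-table-independent motif.
#'
#' @param match_prob Per-column consensus probability (default 0.97).
#' @return A `zf_pwm` with id `"BmMamoS_printed"`.
#' @export
mamo_pwm <- function(match_prob = 0.97) {
  pwm_from_consensus("GTGCGTGGC", match_prob, id = "BmMamoS_printed")
}

#' Consensus sequence of a PWM
#'
#' Per-column argmax base; ties broken alphabetically (A < C < G < T).
#'
#' @param x A `zf_pwm`.
#' @return A DNA string of length `x$width`.
#' @export
consensus <- function(x) {
  stopifnot(inherits(x, "zf_pwm"))
  paste(DNA_BASES[apply(x$probs, 2, which.max)], collapse = "")
}

#' @export
print.zf_pwm <- function(x, ...) {
  cat(sprintf("<zf_pwm> %s  width=%d  pseudocount=%g\n", x$id, x$width,
              x$pseudocount))
  cat("consensus:", consensus(x), "\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' @export
#' @method tidy zf_pwm
tidy.zf_pwm <- function(x, ...) {
  tibble(
    position = rep(seq_len(x$width), each = 4L),
    base = rep(DNA_BASES, x$width),
    prob = as.numeric(x$probs)
  )
}

#' Write a PWM in MEME minimal motif format
#'
#' @param x A `zf_pwm`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(x, path) {
  stopifnot(inherits(x, "zf_pwm"))
  bg <- x$background
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]), "",
    sprintf("MOTIF %s", x$id),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
            x$width),
    apply(x$probs, 2, function(p) sprintf(" %.6f %.6f %.6f %.6f",
                                          p[1], p[2], p[3], p[4]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a PWM from MEME minimal motif format
#'
#' Reads the first motif of a MEME minimal-format file (version 4 header,
#' `letter-probability matrix` block).
#'
#' @param path MEME file path.
#' @inheritParams pwm
#' @return A `zf_pwm`.
#' @export
read_meme <- function(path, pseudocount = 0.25) {
  lines <- readLines(path)
  motif_i <- grep("^MOTIF\\s+", lines)
  if (length(motif_i) == 0L) abort("no MOTIF block found")
  id <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[motif_i[1]])
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) > 0L && bg_i[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[c(2, 4, 6, 8)]))
    if (!anyNA(vals)) bg <- vals
  }
  mat_i <- grep("^letter-probability matrix", lines)
  mat_i <- mat_i[mat_i > motif_i[1]][1]
  if (is.na(mat_i)) abort("no letter-probability matrix found")
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[mat_i]))
  rows <- lines[(mat_i + 1L):(mat_i + w)]
  m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                function(x) as.numeric(x[1:4]), numeric(4)))
  m <- t(m)
  m <- sweep(m, 2, colSums(m), "/")  # absorb fixed-precision rounding
  pwm(m, id = id, background = bg / sum(bg), pseudocount = pseudocount)
}

#' Write / read a PWM as plain TSV
#'
#' Columns: position (1-based), A, C, G, T.
#'
#' @param x A `zf_pwm`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `zf_pwm` for the reader.
#' @export
write_pwm_tsv <- function(x, path) {
  stopifnot(inherits(x, "zf_pwm"))
  df <- data.frame(position = seq_len(x$width), t(x$probs))
  colnames(df) <- c("position", DNA_BASES)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pwm_tsv
#' @param id Motif identifier for the reader.
#' @inheritParams pwm
#' @export
read_pwm_tsv <- function(path, id = "motif", background = rep(0.25, 4),
                         pseudocount = 0.25) {
  df <- read.delim(path, check.names = FALSE, comment.char = "#")
  pwm(t(as.matrix(df[, DNA_BASES])), id = id, background = background,
      pseudocount = pseudocount)
}

#' Plot a PWM as stacked per-position base probabilities
#'
#' @param object A `zf_pwm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot zf_pwm
autoplot.zf_pwm <- function(object, ...) {
  df <- tidy.zf_pwm(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position),
                                   y = .data$prob, fill = .data$base)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "motif position", y = "base probability",
                  title = object$id) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
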