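#' Round half away from zero
#'
#' Percentages in evaluation reports follow the print convention of rounding
#' halves up (96.65 -> 96.7), unlike [base::round()] which rounds halves to
#' even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Text folding used for both extraction and lexicon matching: lower case,
# ASCII-fold the handful of clinical glyphs, collapse whitespace.
fold_text <- function(x) {
  x <- tolower(x)
  x <- gsub("μ|µ", "u", x)  # micro sign
  x <- gsub("×", "x", x)         # multiplication sign
  x <- gsub("³", "3", x)         # superscript three
  x <- gsub("°", "", x)          # degree sign
  x <- gsub("[‘’]", "'", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Aggressive folding for lexicon lookup: also drops punctuation.
# Apostrophes are deleted (murphy's -> murphys), other punctuation becomes
# a word break.
fold_term <- function(x) {
  x <- fold_text(x)
  x <- gsub("'", "", x)
  x <- gsub("[[:punct:]]+", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_tg18 <- function(msg, class) {
  stop(structure(
    class = c(class, "tg18_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

roman_to_int <- function(x) {
  map <- c(i = 1L, ii = 2L, iii = 3L, iv = 4L, v = 5L, vi = 6L)
  x <- tolower(trimws(x))
  out <- suppressWarnings(as.integer(x))
  idx <- is.na(out) & x %in% names(map)
  out[idx] <- map[x[idx]]
  out
}
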