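# Internal helpers shared across modules.

# The 20 canonical amino acids, alphabetical one-letter order. Row order of
# every profile score matrix.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Family labels, in the fixed column order used by every census output.
RQC_FAMILIES <- c("YlmH", "RqcH", "RqcP", "Hsp15", "SmpB")

rqc_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "rqc_error")))
}

# 0-based residue indices for the C++ aligner; X -> 20 (scores 0 bits).
seq_to_idx <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA20) - 1L
  idx[chars == "X"] <- 20L
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    rqc_abort(sprintf("sequence contains non-amino-acid characters: %s",
                      paste(bad, collapse = ", ")),
              "rqc_format_error")
  }
  idx
}

# Evaluate `expr` under a private RNG stream so callers' RNG state is
# untouched and results depend only on `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic small sub-seed (< 2^31) from a base seed and a string tag.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% 32749L
  (abs(as.integer(seed)) %% 65521L) * 32768L + h
}

#' Round half away from zero
#'
#' Rounds to the nearest integer (or given number of digits) with exact
#' halves rounded up, the convention used for displayed incidence
#' percentages (94.74 displays as 95). Base R's `round()` rounds halves to
#' even and is not used for display values.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep (default 0).
#' @return rounded numeric vector.
#' @examples
#' round_half_up(94.74)  # 95
#' round_half_up(0.5)    # 1
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
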