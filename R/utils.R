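#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves carried away from zero
#' (so `round_away(0.5) == 1`, `round_away(-0.5) == -1`), the convention
#' used when reporting headline ratios and per-sample averages. Base R's
#' `round()` rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (may be negative).
#' @return numeric vector of the same length.
#' @export
#' @examples
#' round_away(13.875)       # 14
#' round_away(24.7, 0)      # 25
#' round_away(0.8916667, 1) # 0.9
round_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Normalize chromosome labels: strip a leading "chr"/"Chr" prefix.
norm_chrom <- function(chr) {
  sub("^[Cc][Hh][Rr]", "", as.character(chr))
}

# Deterministic sub-stream seed below 2^31, derived from a base seed.
derive_seed <- function(base, a, b = 0L) {
  as.integer((as.numeric(base) * 7919 + a * 104729 + b * 15485863) %% 2147483587) + 1L
}

# Stop unless a data frame has the named columns.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
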