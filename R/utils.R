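# Internal helpers: display-precision formatting shared by reports and print
# methods. Percentages and ratios print to one decimal, coefficients to two,
# p-values to four decimals or "<0.0001".

fmt_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 1e-4, "<0.0001", formatC(round(p, 4), format = "f", digits = 4)))
}

fmt1 <- function(x) formatC(round(x, 1), format = "f", digits = 1)

fmt2 <- function(x) formatC(round(x, 2), format = "f", digits = 2)

#' @noRd
assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}

# Derive a stream of reproducible sub-seeds from one master seed without
# exhausting 32-bit integer range.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
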