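#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The U statistic
#' uses midranks for ties. The p-value is exact (full enumeration of rank
#' assignments) when both groups have at most `exact_max` observations and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max Largest per-group size for the exact p-value (default 8).
#' @return A one-row tibble with `u` (statistic for `x`), `p_value`, and
#'   `method` (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # two-sided p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  tibble::tibble(u = unname(ht$statistic), p_value = ht$p.value,
                 method = if (exact) "exact" else "normal")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing every hypergeometric table (at the observed
#' margins) whose probability does not exceed the observed table's.
#'
#' @param a,b,c,d Cell counts: `a` exposed/outcome+, `b` exposed/outcome-,
#'   `c` unexposed/outcome+, `d` unexposed/outcome-. A 2x2 matrix may be
#'   passed as `a`.
#' @return A one-row tibble with `p_value`.
#' @examples
#' fisher_exact_2x2(41, 21, 23, 44) # p = 0.0004
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- as_table_2x2(a, b, c, d)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) {
    warning("degenerate margin: p = 1", call. = FALSE)
    return(tibble::tibble(p_value = 1))
  }
  tibble::tibble(p_value = fisher.test(m, alternative = "two.sided")$p.value)
}

# normalize (a,b,c,d) or a matrix into the 2x2 layout
#   outcome+  outcome-
# exposed   a  b
# unexposed c  d
as_table_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2L, 2L)
  if (any(m < 0) || anyNA(m)) stop("cell counts must be non-negative", call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = ad / (bc)` with the 95% interval on the log scale,
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero cell the
#' Haldane 0.5 continuity correction is applied to all cells (with a warning)
#' when `continuity = TRUE`, else it is an error.
#'
#' @inheritParams fisher_exact_2x2
#' @param conf_level Confidence level, default 0.95.
#' @param continuity Apply the 0.5 fallback on zero cells.
#' @return One-row tibble: `or`, `conf_low`, `conf_high`, `conf_level`.
#' @examples
#' odds_ratio(41, 21, 23, 44) # 3.7 (1.8; 7.7)
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL,
                       conf_level = 0.95, continuity = TRUE) {
  m <- as_table_2x2(a, b, c, d)
  if (any(m == 0)) {
    if (!continuity) stop("zero cell: odds ratio undefined without continuity fallback",
                          call. = FALSE)
    warning("zero cell: applying 0.5 continuity correction", call. = FALSE)
    m <- m + 0.5
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / m))
  tibble::tibble(or = or,
                 conf_low = exp(log(or) - z * se),
                 conf_high = exp(log(or) + z * se),
                 conf_level = conf_level)
}

#' Risk ratio with Katz confidence interval
#'
#' `RR = [a/(a+b)] / [c/(c+d)]` with the 95% interval on the log scale using
#' the Katz standard error `sqrt(b/(a(a+b)) + d/(c(c+d)))`.
#'
#' @inheritParams odds_ratio
#' @return One-row tibble: `rr`, `conf_low`, `conf_high`, `conf_level`.
#' @examples
#' risk_ratio(26, 7, 11, 31) # 3.0 (1.8; 5.2)
#' @export
risk_ratio <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  m <- as_table_2x2(a, b, c, d)
  if (m[1, 1] + m[1, 2] == 0 || m[2, 1] + m[2, 2] == 0 || m[2, 1] == 0) {
    stop("risk ratio undefined: zero exposed group or zero unexposed risk",
         call. = FALSE)
  }
  p1 <- m[1, 1] / (m[1, 1] + m[1, 2])
  p0 <- m[2, 1] / (m[2, 1] + m[2, 2])
  rr <- p1 / p0
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(m[1, 2] / (m[1, 1] * (m[1, 1] + m[1, 2])) +
               m[2, 2] / (m[2, 1] * (m[2, 1] + m[2, 2])))
  tibble::tibble(rr = rr,
                 conf_low = exp(log(rr) - z * se),
                 conf_high = exp(log(rr) + z * se),
                 conf_level = conf_level)
}

#' Unscaled median absolute deviation
#'
#' `median(|x - median(x)|)` with no consistency constant — the dispersion
#' summary used for the phase-wise attenuation comparison.
#'
#' @param x Numeric sample, non-empty; `NA` removed if `na.rm = TRUE`.
#' @param na.rm Drop missing values first.
#' @return Scalar MAD.
#' @examples
#' mad_unscaled(c(1, 2, 3, 4, 100)) # 1
#' @export
mad_unscaled <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) stop("sample must be non-empty", call. = FALSE)
  mad(x, constant = 1)
}

#' Diagnostic parameters of a 2x2 classification table
#'
#' Sensitivity `a/(a+c)`, specificity `d/(b+d)`, positive and negative
#' predictive values `a/(a+b)`, `d/(c+d)`, and accuracy `(a+d)/n`, with the
#' table laid out as test-positive/negative (rows) by outcome+/- (columns):
#' `a` = test+/outcome+, `b` = test+/outcome-, `c` = test-/outcome+,
#' `d` = test-/outcome-.
#'
#' @inheritParams fisher_exact_2x2
#' @return One-row tibble with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`; a ratio with zero denominator is `NA`.
#' @examples
#' diagnostic_parameters(41, 21, 23, 44)
#' @export
diagnostic_parameters <- function(a, b = NULL, c = NULL, d = NULL) {
  m <- as_table_2x2(a, b, c, d)
  if (sum(m) == 0) stop("empty table", call. = FALSE)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  tibble::tibble(
    sensitivity = ratio(a, a + c),
    specificity = ratio(d, b + d),
    ppv = ratio(a, a + b),
    npv = ratio(d, c + d),
    accuracy = (a + d) / sum(m)
  )
}
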