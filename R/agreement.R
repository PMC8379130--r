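#' Wilcoxon signed-rank test for paired readings
#'
#' Two-sided matched-pairs test of a systematic difference between two
#' readers. Zero differences are excluded; ties among the remaining absolute
#' differences take midranks. The p-value is exact (sign-assignment
#' enumeration) when at most `exact_max` nonzero differences remain and there
#' are no ties, otherwise the normal approximation with continuity correction
#' is used. With no nonzero difference at all, p = 1 with a warning.
#'
#' @param reader1,reader2 Numeric vectors of equal length, aligned by lesion.
#' @param exact_max Largest number of nonzero differences for the exact test
#'   (default 12).
#' @return One-row tibble: `statistic` (V), `p_value`, `n_nonzero`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(1.2, 2.1, 3.4, 4.1, 5.3))
#' @export
wilcoxon_signed_rank <- function(reader1, reader2, exact_max = 12L) {
  if (length(reader1) != length(reader2)) {
    stop("readers must have the same number of lesions", call. = FALSE)
  }
  d <- reader1 - reader2
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0L) {
    warning("no nonzero differences: p = 1", call. = FALSE)
    return(tibble::tibble(statistic = 0, p_value = 1, n_nonzero = 0L,
                          method = "degenerate"))
  }
  ties <- anyDuplicated(abs(nz)) > 0L
  exact <- !ties && length(nz) <= exact_max
  ht <- suppressWarnings(
    wilcox.test(nz, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_nonzero = length(nz), method = if (exact) "exact" else "normal")
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement ICC for two
#' readers measuring the same lesions — the standard reliability form for a
#' fixed pair of human readers — computed from the mean squares of the
#' two-way (lesion x reader) decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#'
#' @param reader1,reader2 Numeric vectors of equal length (>= 3 lesions).
#' @return One-row tibble: `icc`, `n`, plus a `degenerate` flag when the
#'   between-lesion variance is zero.
#' @examples
#' icc(c(100, 110, 120, 130), c(101, 112, 119, 133))
#' @export
icc <- function(reader1, reader2) {
  if (length(reader1) != length(reader2)) {
    stop("readers must have the same number of lesions", call. = FALSE)
  }
  ok <- complete.cases(reader1, reader2)
  x <- cbind(reader1[ok], reader2[ok])
  n <- nrow(x); k <- 2
  if (n < 3L) stop("need at least 3 lesions", call. = FALSE)

  row_m <- rowMeans(x); col_m <- colMeans(x); grand <- mean(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)              # between lesions
  msc <- n * sum((col_m - grand)^2) / (k - 1)              # between readers
  mse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  degenerate <- msr < .Machine$double.eps^0.5 * max(1, grand^2)
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  if (degenerate) {
    warning("zero between-lesion variance: ICC degenerate", call. = FALSE)
  }
  tibble::tibble(icc = val, n = n, degenerate = degenerate)
}

#' Two-rater Cronbach's alpha
#'
#' Internal-consistency coefficient for two readers,
#' `2 * (1 - (V1 + V2) / V_sum)` where `V1`, `V2` are the per-reader
#' variances and `V_sum` the variance of the per-lesion sums — Cronbach's
#' alpha with k = 2 items. Equals 1 for identical readings and is near 0 for
#' independent ones (it can be negative).
#'
#' @param reader1,reader2 Numeric vectors of equal length (>= 3 lesions).
#' @return One-row tibble: `alpha`, `n`, `degenerate` flag (zero total
#'   variance).
#' @examples
#' cronbach_coefficient(c(100, 110, 120), c(102, 109, 121))
#' @export
cronbach_coefficient <- function(reader1, reader2) {
  if (length(reader1) != length(reader2)) {
    stop("readers must have the same number of lesions", call. = FALSE)
  }
  ok <- complete.cases(reader1, reader2)
  r1 <- reader1[ok]; r2 <- reader2[ok]
  n <- length(r1)
  if (n < 3L) stop("need at least 3 lesions", call. = FALSE)
  v_sum <- var(r1 + r2)
  if (v_sum < .Machine$double.eps) {
    warning("zero total variance: alpha degenerate", call. = FALSE)
    return(tibble::tibble(alpha = NA_real_, n = n, degenerate = TRUE))
  }
  tibble::tibble(alpha = 2 * (1 - (var(r1) + var(r2)) / v_sum),
                 n = n, degenerate = FALSE)
}

#' Cohen's kappa for categorical calls
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the product of the two readers' marginal distributions.
#'
#' @param reader1,reader2 Vectors of categorical calls (character or factor),
#'   equal length.
#' @return One-row tibble: `kappa`, `p_observed`, `p_expected`, `n`, and a
#'   `degenerate` flag when `p_e = 1` (a single shared category).
#' @examples
#' cohen_kappa(rep(c("smooth", "other"), c(25, 25)),
#'             rep(c("smooth", "other", "smooth", "other"), c(20, 5, 5, 20)))
#' @export
cohen_kappa <- function(reader1, reader2) {
  if (length(reader1) != length(reader2)) {
    stop("readers must have the same number of lesions", call. = FALSE)
  }
  ok <- !is.na(reader1) & !is.na(reader2)
  r1 <- as.character(reader1[ok]); r2 <- as.character(reader2[ok])
  n <- length(r1)
  cats <- union(unique(r1), unique(r2))
  if (length(cats) < 2L) {
    warning("fewer than 2 observed categories: kappa degenerate", call. = FALSE)
    return(tibble::tibble(kappa = NA_real_, p_observed = 1, p_expected = 1,
                          n = n, degenerate = TRUE))
  }
  p_o <- mean(r1 == r2)
  p_e <- sum(vapply(cats, function(ct) mean(r1 == ct) * mean(r2 == ct), numeric(1)))
  if (1 - p_e < .Machine$double.eps) {
    warning("expected agreement is 1: kappa degenerate", call. = FALSE)
    return(tibble::tibble(kappa = NA_real_, p_observed = p_o, p_expected = p_e,
                          n = n, degenerate = TRUE))
  }
  tibble::tibble(kappa = (p_o - p_e) / (1 - p_e), p_observed = p_o,
                 p_expected = p_e, n = n, degenerate = FALSE)
}

#' Inter-reader agreement table for two lesion tables
#'
#' Convenience wrapper producing a per-variable agreement report between two
#' readers' lesion tables (aligned by `lesion_id`): Wilcoxon matched-pairs p,
#' ICC(2,1) and Cronbach's alpha for each quantitative index, and Cohen's
#' kappa for the margins call.
#'
#' @param reader1,reader2 Lesion tables (see [generate_cohort()]); indices
#'   are computed via [add_enhancement_indices()] if absent.
#' @param variables Quantitative index columns to compare.
#' @param margins Also compare the categorical margins call.
#' @return A tibble with one row per variable: `variable`, `type`,
#'   `wilcoxon_p`, `icc`, `cronbach_alpha`, `kappa`.
#' @export
agreement_table <- function(reader1, reader2,
                            variables = c("cer", "llc", "wo_abs", "wo_rel", "dpar"),
                            margins = TRUE) {
  prep <- function(d) {
    d <- tibble::as_tibble(d)
    if (!all(variables %in% names(d))) d <- add_enhancement_indices(d)
    d
  }
  r1 <- prep(reader1); r2 <- prep(reader2)
  if ("lesion_id" %in% names(r1) && "lesion_id" %in% names(r2)) {
    r2 <- r2[match(r1$lesion_id, r2$lesion_id), ]
  }
  if (nrow(r1) != nrow(r2)) stop("reader tables must cover the same lesions", call. = FALSE)

  rows <- purrr::map(variables, function(v) {
    tibble::tibble(
      variable = v, type = "quantitative",
      wilcoxon_p = wilcoxon_signed_rank(r1[[v]], r2[[v]])$p_value,
      icc = icc(r1[[v]], r2[[v]])$icc,
      cronbach_alpha = cronbach_coefficient(r1[[v]], r2[[v]])$alpha,
      kappa = NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  if (margins && "margins" %in% names(r1)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      variable = "margins", type = "categorical",
      wilcoxon_p = NA_real_, icc = NA_real_, cronbach_alpha = NA_real_,
      kappa = cohen_kappa(r1$margins, r2$margins)$kappa
    ))
  }
  out
}
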