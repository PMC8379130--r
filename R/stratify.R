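#' Stratify lesions by DPAR threshold and margins
#'
#' Cross-tabulates the two favorable predictors — DPAR at or above the
#' threshold and smooth margins — against complete response, reporting the
#' complete-response count and rate in each of the four cells, the pooled
#' rate of the two single-predictor cells, and the odds and risk ratios of
#' the two extreme cells (both predictors vs neither). Lesions with a
#' non-evaluable (missing) DPAR are excluded and counted.
#'
#' @param data Lesion table containing `margins`, `response`, and a DPAR
#'   column (computed via [add_enhancement_indices()] if absent).
#' @param threshold DPAR dichotomization threshold (inclusive), default 120.
#' @return A `lesion_strata` object: list with `cells` (tibble: `dpar_high`,
#'   `smooth`, `n`, `n_cr`, `cr_rate`), `pooled_one_predictor` (n, n_cr,
#'   rate), `odds_ratio` and `risk_ratio` tibbles for the extreme-cell
#'   comparison, `n_excluded`, and `threshold`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' stratify_lesions(generate_cohort())
#' @export
stratify_lesions <- function(data, threshold = 120) {
  data <- tibble::as_tibble(data)
  if (!"dpar" %in% names(data)) data <- add_enhancement_indices(data)
  assert_cols(data, c("dpar", "margins", "response"), "lesion table")

  excluded <- is.na(data$dpar)
  d <- data[!excluded, ]
  d$dpar_high <- dichotomize_dpar(d$dpar, threshold) == "high"
  d$smooth <- d$margins == "smooth"
  d$cr <- dichotomize_response(d$response) == "CR+"

  cells <- tidyr::complete(
    dplyr::summarise(dplyr::group_by(d, .data$dpar_high, .data$smooth),
                     n = dplyr::n(), n_cr = sum(.data$cr), .groups = "drop"),
    dpar_high = c(TRUE, FALSE), smooth = c(TRUE, FALSE),
    fill = list(n = 0L, n_cr = 0L)
  )
  cells <- dplyr::arrange(cells, dplyr::desc(.data$dpar_high), dplyr::desc(.data$smooth))
  cells$cr_rate <- ifelse(cells$n > 0, cells$n_cr / cells$n, NA_real_)

  cell <- function(hi, sm) cells[cells$dpar_high == hi & cells$smooth == sm, ]
  both <- cell(TRUE, TRUE); neither <- cell(FALSE, FALSE)
  one <- dplyr::bind_rows(cell(TRUE, FALSE), cell(FALSE, TRUE))
  pooled <- tibble::tibble(n = sum(one$n), n_cr = sum(one$n_cr),
                           cr_rate = ifelse(sum(one$n) > 0,
                                            sum(one$n_cr) / sum(one$n), NA_real_))

  extreme_or <- extreme_rr <- NULL
  if (both$n > 0 && neither$n > 0 && neither$n_cr > 0) {
    a <- both$n_cr; b <- both$n - both$n_cr
    c_ <- neither$n_cr; d_ <- neither$n - neither$n_cr
    if (all(c(a, b, c_, d_) > 0)) extreme_or <- odds_ratio(a, b, c_, d_)
    extreme_rr <- risk_ratio(a, b, c_, d_)
  }

  structure(
    list(cells = cells, pooled_one_predictor = pooled,
         odds_ratio = extreme_or, risk_ratio = extreme_rr,
         n_excluded = sum(excluded), threshold = threshold),
    class = "lesion_strata"
  )
}

#' @rdname stratify_lesions
#' @param x A `lesion_strata` object.
#' @param ... Unused.
#' @export
tidy.lesion_strata <- function(x, ...) x$cells

#' @rdname stratify_lesions
#' @export
glance.lesion_strata <- function(x, ...) {
  tibble::tibble(
    n = sum(x$cells$n),
    n_cr = sum(x$cells$n_cr),
    n_excluded = x$n_excluded,
    threshold = x$threshold,
    pooled_one_predictor_rate = x$pooled_one_predictor$cr_rate,
    extreme_or = if (is.null(x$odds_ratio)) NA_real_ else x$odds_ratio$or,
    extreme_rr = if (is.null(x$risk_ratio)) NA_real_ else x$risk_ratio$rr
  )
}

#' @export
print.lesion_strata <- function(x, ...) {
  cat(sprintf("Lesion stratification at DPAR >= %s (n = %d, %d excluded)\n",
              format(x$threshold), sum(x$cells$n), x$n_excluded))
  lab <- function(hi, sm) paste0("DPAR ", if (hi) ">= " else "< ", format(x$threshold),
                                 ", ", if (sm) "smooth" else "other", " margins")
  for (i in seq_len(nrow(x$cells))) {
    cc <- x$cells[i, ]
    cat(sprintf("  %-28s CR+ %d/%d = %s%%\n", lab(cc$dpar_high, cc$smooth),
                cc$n_cr, cc$n, fmt1(100 * cc$cr_rate)))
  }
  cat(sprintf("  one favorable predictor (pooled): %d/%d = %s%%\n",
              x$pooled_one_predictor$n_cr, x$pooled_one_predictor$n,
              fmt1(100 * x$pooled_one_predictor$cr_rate)))
  if (!is.null(x$odds_ratio)) {
    cat(sprintf("  both vs neither: OR %s (%s; %s), RR %s (%s; %s)\n",
                fmt1(x$odds_ratio$or), fmt1(x$odds_ratio$conf_low),
                fmt1(x$odds_ratio$conf_high), fmt1(x$risk_ratio$rr),
                fmt1(x$risk_ratio$conf_low), fmt1(x$risk_ratio$conf_high)))
  }
  invisible(x)
}

#' @rdname stratify_lesions
#' @param object A `lesion_strata` object.
#' @export
autoplot.lesion_strata <- function(object, ...) {
  d <- object$cells
  d$cell <- factor(
    paste0("DPAR ", ifelse(d$dpar_high, "≥", "<"), format(object$threshold),
           "\n", ifelse(d$smooth, "smooth", "other")),
    levels = paste0("DPAR ", c("≥", "≥", "<", "<"), format(object$threshold),
                    "\n", c("smooth", "other", "smooth", "other"))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cell, y = 100 * .data$cr_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$n_cr, .data$n)),
                       vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "CR+ rate (%)",
                  title = "Complete response by preprocedural CT outcome") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}
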