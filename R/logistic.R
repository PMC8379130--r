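#' Binary logistic regression with Wald odds-ratio intervals
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' (convergence tolerance 1e-10, at most 100 iterations), with Wald standard
#' errors and per-predictor odds ratios with 95% confidence intervals — the
#' multivariate step run on predictors found significant univariately.
#' Complete or quasi-complete separation is detected and raised as an error
#' naming the offending predictor rather than returning a divergent fit.
#'
#' @param data Data frame, one row per lesion.
#' @param formula Model formula; the left-hand side must be binary (logical,
#'   0/1, or a two-level factor whose *first* level is treated as the
#'   positive class — note this matches `"CR+"`/`"CR-"` factors from
#'   [dichotomize_response()]).
#' @param conf_level Confidence level for the odds-ratio intervals.
#' @return A `blr_fit` object wrapping the `glm` fit. [tidy()] returns
#'   per-term estimates, Wald statistics and OR intervals; [glance()] returns
#'   fit-level diagnostics (n, deviance, convergence, iterations).
#' @examples
#' cohort <- generate_cohort() |> add_enhancement_indices()
#' cohort$cr <- dichotomize_response(cohort$response) == "CR+"
#' cohort$dpar_high <- dichotomize_dpar(cohort$dpar) == "high"
#' fit <- logistic_fit(cohort, cr ~ dpar_high + margins)
#' tidy(fit)
#' @export
logistic_fit <- function(data, formula, conf_level = 0.95) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2L) stop("outcome must have two levels", call. = FALSE)
    # first level = positive class (CR+ convention)
    mf[[1]] <- as.integer(y == levels(y)[1])
  } else if (is.logical(y)) {
    mf[[1]] <- as.integer(y)
  } else if (!all(y %in% c(0, 1))) {
    stop("outcome must be binary (logical, 0/1, or two-level factor)", call. = FALSE)
  }

  fit <- suppressWarnings(
    glm(formula(stats::terms(mf)), family = binomial(), data = mf,
        control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  if (!fit$converged) {
    stop("logistic fit did not converge in 100 IRLS iterations; deviance trace: ",
         fmt2(fit$deviance), call. = FALSE)
  }
  eta <- fit$fitted.values
  if (any(eta < 1e-8 | eta > 1 - 1e-8)) {
    cf <- coef(fit)[-1]
    worst <- names(cf)[which.max(abs(cf))]
    stop("complete or quasi-complete separation detected (predictor: ",
         worst, ")", call. = FALSE)
  }
  structure(list(fit = fit, conf_level = conf_level, formula = formula),
            class = "blr_fit")
}

#' @rdname logistic_fit
#' @param x A `blr_fit`.
#' @param ... Unused.
#' @export
tidy.blr_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  tibble::tibble(
    term = rownames(cf),
    estimate = unname(cf[, "Estimate"]),
    std_error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "z value"]),
    p_value = unname(cf[, "Pr(>|z|)"]),
    odds_ratio = exp(unname(cf[, "Estimate"])),
    conf_low = exp(unname(cf[, "Estimate"] - z * cf[, "Std. Error"])),
    conf_high = exp(unname(cf[, "Estimate"] + z * cf[, "Std. Error"]))
  )
}

#' @rdname logistic_fit
#' @export
glance.blr_fit <- function(x, ...) {
  tibble::tibble(
    n = stats::nobs(x$fit),
    null_deviance = x$fit$null.deviance,
    deviance = x$fit$deviance,
    aic = x$fit$aic,
    converged = x$fit$converged,
    iterations = x$fit$iter
  )
}

#' @export
print.blr_fit <- function(x, ...) {
  td <- tidy(x)
  cat("Binary logistic regression:", deparse(x$formula), "\n")
  for (i in seq_len(nrow(td))[-1]) {
    cat(sprintf("  %s: OR %s (%s-%s), p %s\n", td$term[i], fmt1(td$odds_ratio[i]),
                fmt1(td$conf_low[i]), fmt1(td$conf_high[i]), fmt_p(td$p_value[i])))
  }
  invisible(x)
}
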