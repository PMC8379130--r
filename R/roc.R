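#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC curve of a continuous score against a binary
#' outcome (direction fixed: higher score indicates the positive class, the
#' convention for wash-out indices and complete response). Classification at
#' threshold `t` is score `>= t`. The AUC is the trapezoidal area, which
#' equals the tie-corrected concordance probability
#' (concordant pairs + half ties) / (n+ x n-), and the confidence interval is
#' computed by DeLong's method.
#'
#' @param data Data frame with one row per lesion.
#' @param score,outcome Unquoted column names: the continuous score and the
#'   binary outcome.
#' @param positive Value of `outcome` denoting the positive class. Defaults
#'   to `TRUE` for logical outcomes and `"CR+"` when present; otherwise
#'   required.
#' @param conf_level Confidence level for the AUC interval.
#' @return A `washout_roc` object: list with `curve` (tibble of `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `conf_low`, `conf_high`, `n_pos`,
#'   `n_neg`. Supports [tidy()], [glance()] and [autoplot()]. Rows with a
#'   missing score or outcome are dropped with a message.
#' @examples
#' cohort <- generate_cohort() |> add_enhancement_indices()
#' cohort$cr <- dichotomize_response(cohort$response)
#' roc_auc(cohort, dpar, cr)
#' @export
roc_auc <- function(data, score, outcome, positive = NULL, conf_level = 0.95) {
  s <- dplyr::pull(data, {{ score }})
  y <- dplyr::pull(data, {{ outcome }})
  keep <- !is.na(s) & !is.na(y)
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing score or outcome dropped")
    s <- s[keep]; y <- y[keep]
  }
  pos <- roc_positive_class(y, positive)
  is_pos <- y == pos
  if (all(is_pos) || all(!is_pos)) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  x_pos <- s[is_pos]
  x_neg <- s[!is_pos]

  # curve over distinct thresholds, descending, with (0,1)/(1,0) endpoints
  thr <- sort(unique(s), decreasing = TRUE)
  sens <- vapply(thr, function(t) mean(x_pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(x_neg < t), numeric(1))
  curve <- tibble::tibble(
    threshold = c(Inf, thr, -Inf),
    sensitivity = c(0, sens, 1),
    specificity = c(1, spec, 0)
  )
  fpr <- 1 - curve$specificity
  auc <- sum(diff(fpr) * (head(curve$sensitivity, -1) + curve$sensitivity[-1]) / 2)

  ci <- delong_ci(x_pos, x_neg, auc, conf_level)
  structure(
    list(curve = curve, auc = auc,
         conf_low = ci[1], conf_high = ci[2], conf_level = conf_level,
         n_pos = length(x_pos), n_neg = length(x_neg),
         positive = pos, scores = s, is_pos = is_pos),
    class = "washout_roc"
  )
}

roc_positive_class <- function(y, positive) {
  if (!is.null(positive)) return(positive)
  if (is.logical(y)) return(TRUE)
  vals <- unique(as.character(y))
  if ("CR+" %in% vals) return("CR+")
  stop("specify `positive =` for outcome values: ", paste(vals, collapse = ", "),
       call. = FALSE)
}

# DeLong variance of the empirical AUC via placement values
delong_ci <- function(x_pos, x_neg, auc, conf_level) {
  m <- length(x_pos); n <- length(x_neg)
  if (m < 2L || n < 2L) return(c(NA_real_, NA_real_))
  v10 <- vapply(x_pos, function(x) mean((x > x_neg) + 0.5 * (x == x_neg)), numeric(1))
  v01 <- vapply(x_neg, function(y) mean((x_pos > y) + 0.5 * (x_pos == y)), numeric(1))
  se <- sqrt(var(v10) / m + var(v01) / n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
}

#' @export
print.washout_roc <- function(x, ...) {
  cat("Empirical ROC: ", x$n_pos, " positive / ", x$n_neg, " negative\n", sep = "")
  cat("AUC = ", fmt2(x$auc), " (", round(100 * x$conf_level), "% CI ",
      fmt2(x$conf_low), "-", fmt2(x$conf_high), ", DeLong)\n", sep = "")
  invisible(x)
}

#' @rdname roc_auc
#' @param x A `washout_roc` object.
#' @param ... Unused.
#' @export
tidy.washout_roc <- function(x, ...) x$curve

#' @rdname roc_auc
#' @export
glance.washout_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, conf_low = x$conf_low, conf_high = x$conf_high,
                 conf_level = x$conf_level, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname roc_auc
#' @param object A `washout_roc` object.
#' @export
autoplot.washout_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC = %s (%d%% CI %s-%s)", fmt2(object$auc),
                      round(100 * object$conf_level),
                      fmt2(object$conf_low), fmt2(object$conf_high))
    ) +
    ggplot2::theme_minimal()
}

#' Select a dichotomization threshold from an ROC curve
#'
#' Scans every distinct score value as a `>=` cut and selects the optimum
#' under three criteria: maximum Youden index (sens + spec - 1), maximum
#' harmonic mean of sensitivity and specificity, and minimum Euclidean
#' distance of the curve point from the upper-left corner. Ties within a
#' criterion are broken toward the higher (more specific) cut. The reported
#' threshold for each criterion is the midpoint of the score interval over
#' which the optimal confusion table holds (so for perfectly separated
#' classes it is the midpoint of the separating gap); the raw optimal cut is
#' also returned. The consensus is the common value when all three criteria
#' agree, otherwise the Youden threshold.
#'
#' @param roc A `washout_roc` from [roc_auc()].
#' @return A one-row tibble with columns `by_youden`, `by_harmonic_mean`,
#'   `by_corner_distance`, `consensus`, `agreement` (logical: all three
#'   agree), and the raw cuts `cut_youden`, `cut_harmonic_mean`,
#'   `cut_corner_distance`.
#' @examples
#' cohort <- generate_cohort() |> add_enhancement_indices()
#' cohort$cr <- dichotomize_response(cohort$response)
#' select_threshold(roc_auc(cohort, dpar, cr))
#' @export
select_threshold <- function(roc) {
  stopifnot(inherits(roc, "washout_roc"))
  s <- roc$scores; is_pos <- roc$is_pos
  cuts <- sort(unique(s)) # ascending: ties broken toward higher cut via which.max on reversed? handled below
  sens <- vapply(cuts, function(t) mean(s[is_pos] >= t), numeric(1))
  spec <- vapply(cuts, function(t) mean(s[!is_pos] < t), numeric(1))

  youden <- sens + spec - 1
  hmean <- ifelse(sens + spec > 0, 2 * sens * spec / (sens + spec), 0)
  corner <- -sqrt((1 - sens)^2 + (1 - spec)^2) # maximize
  pick <- function(crit) {
    best <- which(crit >= max(crit) - 1e-12)
    cuts[max(best)] # highest cut among ties
  }
  raw <- c(youden = pick(youden), harmonic_mean = pick(hmean),
           corner_distance = pick(corner))
  # midpoint of the constant-classification interval (prev distinct score, cut]
  mid <- vapply(raw, function(ct) {
    below <- cuts[cuts < ct]
    if (length(below) == 0L) ct else (ct + max(below)) / 2
  }, numeric(1))

  agreement <- length(unique(mid)) == 1L
  tibble::tibble(
    by_youden = mid[["youden"]],
    by_harmonic_mean = mid[["harmonic_mean"]],
    by_corner_distance = mid[["corner_distance"]],
    consensus = if (agreement) mid[["youden"]] else mid[["youden"]],
    agreement = agreement,
    cut_youden = raw[["youden"]],
    cut_harmonic_mean = raw[["harmonic_mean"]],
    cut_corner_distance = raw[["corner_distance"]]
  )
}
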