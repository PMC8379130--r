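#' Calibration defaults for the synthetic cohort generator
#'
#' Returns the summary statistics the generator reproduces: per-response-group
#' DPAR quartiles and exceedance probabilities at the 120 threshold, the joint
#' counts of (DPAR >= 120) x margins x complete response for the 129-lesion
#' reference cohort, the mRECIST response mix, diameter quartiles per group,
#' and the overall lesion-location mix. Override individual entries to
#' simulate other study conditions.
#'
#' @return A named list; see entries in the source for the structure.
#' @export
default_calibration <- function() {
  list(
    dpar = list(
      `CR+` = list(quartiles = c(116, 124, 139), exceedance_120 = 41 / 64),
      `CR-` = list(quartiles = c(108, 115, 123), exceedance_120 = 21 / 65)
    ),
    dpar_threshold = 120,
    # joint cells: DPAR >= 120 (high) x smooth margins, with CR+ counts
    cells = tibble::tibble(
      dpar_high = c(TRUE, TRUE, FALSE, FALSE),
      smooth = c(TRUE, FALSE, TRUE, FALSE),
      n = c(33L, 29L, 25L, 42L),
      n_cr = c(26L, 15L, 12L, 11L)
    ),
    response_mix = c(CR = 64L, PR = 53L, SD = 7L, PD = 5L),
    diameter_mm = list(
      `CR+` = c(14, 19, 25.5),
      `CR-` = c(16, 23, 33)
    ),
    location_mix = c(right = 81L, median = 23L, left = 25L),
    # HU synthesis: unenhanced lesion baseline and wash-in index quartiles
    ue_mean = 55, ue_sd = 7,
    cer = list(`CR+` = c(110, 150, 210), `CR-` = c(130, 150, 180)),
    llc = list(`CR+` = c(50, 70, 90), `CR-` = c(50, 70, 100)),
    wo_rel = list(`CR+` = c(18, 27, 35), `CR-` = c(10, 22, 32)),
    cer_worel_rho = 0.7,
    liver_roi_split_sd = 2
  )
}

# Monotone piecewise-linear quantile function through (0.25, q1), (0.5, med),
# (0.75, q3) and optional extra (p, value) knots, with exponential tails below
# Q1 / above Q3 whose scales match the density of the adjacent linear piece.
# Returns list(Q = quantile fn, F = cdf).
piecewise_quantile <- function(quartiles, extra_knots = NULL) {
  q1 <- quartiles[1]; med <- quartiles[2]; q3 <- quartiles[3]
  if (!(q1 < med && med < q3)) stop("calibration quartiles must be strictly increasing",
                                    call. = FALSE)
  p <- c(0.25, 0.5, 0.75)
  v <- c(q1, med, q3)
  if (!is.null(extra_knots)) {
    p <- c(p, extra_knots$p)
    v <- c(v, extra_knots$value)
    o <- order(p)
    p <- p[o]; v <- v[o]
    if (any(diff(v) <= 0)) stop("knots not monotone with calibration quartiles",
                                call. = FALSE)
  }
  s_lo <- 0.25 * (v[2] - v[1]) / (p[2] - p[1]) # tail scale, density-matched
  k <- length(p)
  s_hi <- 0.25 * (v[k] - v[k - 1]) / (p[k] - p[k - 1])

  Qfun <- function(u) {
    out <- numeric(length(u))
    lo <- u < 0.25
    hi <- u > 0.75
    mid <- !lo & !hi
    out[mid] <- stats::approx(p, v, xout = u[mid], rule = 2)$y
    out[lo] <- q1 + s_lo * log(u[lo] / 0.25)
    out[hi] <- q3 - s_hi * log((1 - u[hi]) / 0.25)
    out
  }
  Ffun <- function(x) {
    out <- numeric(length(x))
    lo <- x < q1
    hi <- x > q3
    mid <- !lo & !hi
    out[mid] <- stats::approx(v, p, xout = x[mid], rule = 2, ties = "ordered")$y
    out[lo] <- 0.25 * exp((x[lo] - q1) / s_lo)
    out[hi] <- 1 - 0.25 * exp(-(x[hi] - q3) / s_hi)
    out
  }
  list(Q = Qfun, F = Ffun)
}

# DPAR sampler for one response group: quartile-anchored with an exceedance
# knot at the threshold so P(DPAR >= threshold) matches the calibrated value
# exactly in population. The threshold lies inside the interquartile range for
# both groups, so the exceedance is carried by the knot, not the tails.
dpar_sampler <- function(group = c("CR+", "CR-"), calibration = default_calibration()) {
  group <- match.arg(group)
  cal <- calibration$dpar[[group]]
  thr <- calibration$dpar_threshold
  piecewise_quantile(cal$quartiles,
                     extra_knots = list(p = 1 - cal$exceedance_120, value = thr))
}

#' Sample synthetic DPAR values for a response group
#'
#' Draws from a quantile-calibrated distribution whose population quartiles
#' equal the group's reference quartiles (CR+: 116/124/139; CR-: 108/115/123)
#' and whose population exceedance at the 120 threshold equals the reference
#' rate (41/64 for CR+, 21/65 for CR-). The quantile function is monotone
#' piecewise-linear through those anchors with density-matched exponential
#' tails outside the interquartile range.
#'
#' @param n Number of draws (>= 1).
#' @param group `"CR+"` (complete response) or `"CR-"`.
#' @param seed Optional integer seed for reproducibility.
#' @param side Restrict draws relative to the threshold: `"any"` (default),
#'   `"high"` (>= threshold) or `"low"` (< threshold), via inverse-CDF
#'   truncation.
#' @param calibration See [default_calibration()].
#' @return Numeric vector of DPAR values.
#' @examples
#' quantile(sample_dpar(1e4, "CR+", seed = 1), c(.25, .5, .75))
#' @export
sample_dpar <- function(n, group = c("CR+", "CR-"), seed = NULL,
                        side = c("any", "high", "low"),
                        calibration = default_calibration()) {
  group <- match.arg(group)
  side <- match.arg(side)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- dpar_sampler(group, calibration)
  p_thr <- 1 - calibration$dpar[[group]]$exceedance_120
  u <- switch(side,
    any = runif(n),
    high = runif(n, p_thr, 1),
    low = runif(n, 0, p_thr)
  )
  s$Q(u)
}

# Draw from a plain quartile-calibrated sampler (no exceedance knot);
# uniforms may be supplied to impose copula dependence.
sample_quartile <- function(n, quartiles, u = NULL) {
  s <- piecewise_quantile(quartiles)
  s$Q(u %||% runif(n))
}

#' Generate a synthetic lesion cohort
#'
#' Builds a per-lesion table with the joint structure of the reference
#' 129-lesion DEB-TACE cohort: the four (DPAR >= 120) x margins cells with
#' their complete-response counts, group-calibrated continuous DPAR (drawn
#' truncated to the correct side of the threshold for each cell), diameters,
#' mRECIST categories, locations, and a full five-value HU profile per lesion
#' reconstructed from sampled wash-in/wash-out indices (so that
#' [add_enhancement_indices()] on the table recovers the sampled indices).
#'
#' In `"exact_counts"` mode all cell counts match the calibration verbatim
#' (requires `n_lesions` equal to the calibration total, default 129); in
#' `"sampled"` mode cells are drawn multinomially and response within cell is
#' Bernoulli at the cell rate.
#'
#' CER and relative wash-out are drawn with positive rank dependence
#' (Gaussian copula) so strongly arterialized lesions also wash out more;
#' this reproduces the characteristic phase-dispersion ordering
#' MAD(arterial) > MAD(delayed) > MAD(unenhanced).
#'
#' @param n_lesions Cohort size; >= 8 in sampled mode.
#' @param mode `"exact_counts"` or `"sampled"`.
#' @param seed Integer seed; the default gives a fixed reference cohort.
#' @param calibration See [default_calibration()].
#' @return A tibble, one row per lesion, in the standard lesion-table layout
#'   (`lesion_id`, `patient_id`, HU columns, `margins`, `diameter_mm`,
#'   `location`, `response`), with attribute `generator` recording seed,
#'   mode and version.
#' @examples
#' cohort <- generate_cohort()
#' table(dichotomize_response(cohort$response))
#' @export
generate_cohort <- function(n_lesions = 129L,
                            mode = c("exact_counts", "sampled"),
                            seed = 20160101L,
                            calibration = default_calibration()) {
  mode <- match.arg(mode)
  cal <- calibration
  cells <- cal$cells
  for (g in names(cal$dpar)) {
    q <- cal$dpar[[g]]$quartiles
    if (any(diff(q) <= 0)) stop("calibration quartiles non-monotone", call. = FALSE)
  }
  set.seed(seed)

  if (mode == "exact_counts") {
    if (n_lesions != sum(cells$n)) {
      stop(sprintf("exact_counts mode requires n_lesions = %d (calibration total)",
                   sum(cells$n)), call. = FALSE)
    }
    per_cell <- purrr::pmap(cells, function(dpar_high, smooth, n, n_cr) {
      tibble::tibble(dpar_high = dpar_high, smooth = smooth,
                     cr = c(rep(TRUE, n_cr), rep(FALSE, n - n_cr)))
    })
    lesions <- dplyr::bind_rows(per_cell)
  } else {
    if (n_lesions < 8) stop("sampled mode requires n_lesions >= 8", call. = FALSE)
    idx <- sample.int(4L, n_lesions, replace = TRUE, prob = cells$n / sum(cells$n))
    lesions <- tibble::tibble(
      dpar_high = cells$dpar_high[idx],
      smooth = cells$smooth[idx],
      cr = rbinom(n_lesions, 1L, (cells$n_cr / cells$n)[idx]) == 1L
    )
  }
  n <- nrow(lesions)
  lesions$group <- ifelse(lesions$cr, "CR+", "CR-")

  # continuous DPAR conditional on (response group, cell side of threshold)
  lesions$dpar_true <- NA_real_
  for (g in c("CR+", "CR-")) {
    for (hi in c(TRUE, FALSE)) {
      sel <- lesions$group == g & lesions$dpar_high == hi
      if (any(sel)) {
        lesions$dpar_true[sel] <- sample_dpar(sum(sel), g,
                                              side = if (hi) "high" else "low",
                                              calibration = cal)
      }
    }
  }

  # mRECIST categories: CR for responders; PR/SD/PD among the rest in the
  # calibrated ratio (exact allocation in exact_counts mode)
  mix <- cal$response_mix[c("PR", "SD", "PD")]
  n_noncr <- sum(!lesions$cr)
  noncr_cats <- if (mode == "exact_counts" && n_noncr == sum(mix)) {
    sample(rep(names(mix), times = mix))
  } else {
    sample(names(mix), n_noncr, replace = TRUE, prob = mix / sum(mix))
  }
  lesions$response <- "CR"
  lesions$response[!lesions$cr] <- noncr_cats

  # diameters and locations
  lesions$diameter_mm <- NA_real_
  for (g in c("CR+", "CR-")) {
    sel <- lesions$group == g
    lesions$diameter_mm[sel] <- round(sample_quartile(sum(sel), cal$diameter_mm[[g]]), 1)
  }
  loc <- cal$location_mix
  lesions$location <- if (n == sum(loc)) {
    sample(rep(names(loc), times = loc))
  } else {
    sample(names(loc), n, replace = TRUE, prob = loc / sum(loc))
  }

  # HU profiles: draw wash-in/wash-out indices (CER and WO_rel comonotone via
  # a Gaussian copula) and invert the index system around a UE anchor
  z1 <- rnorm(n); z2 <- rnorm(n)
  rho <- cal$cer_worel_rho
  u_cer <- pnorm(z1)
  u_wor <- pnorm(rho * z1 + sqrt(1 - rho^2) * z2)
  cer <- wo_rel <- llc <- numeric(n)
  for (g in c("CR+", "CR-")) {
    sel <- lesions$group == g
    cer[sel] <- sample_quartile(sum(sel), cal$cer[[g]], u = u_cer[sel])
    wo_rel[sel] <- sample_quartile(sum(sel), cal$wo_rel[[g]], u = u_wor[sel])
    llc[sel] <- sample_quartile(sum(sel), cal$llc[[g]])
  }
  # physiologic clamps on the exponential tails (far outside every calibrated
  # IQR, so population quartiles are unaffected): keep ART, DEL, LIVART > 0
  cer <- pmax(pmin(cer, 500), 10)
  wo_rel <- pmax(pmin(wo_rel, 85), -60)
  llc <- pmax(pmin(llc, 400), -60)
  ue <- pmax(rnorm(n, cal$ue_mean, cal$ue_sd), 20)
  art <- ue * (1 + cer / 100)
  liver_art <- art / (1 + llc / 100)
  del <- art * (1 - wo_rel / 100)
  liver_del <- del * lesions$dpar_true / 100
  d_art <- rnorm(n, 0, cal$liver_roi_split_sd)
  d_del <- rnorm(n, 0, cal$liver_roi_split_sd)

  out <- tibble::tibble(
    lesion_id = sprintf("L%03d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    hu_lesion_ue = ue,
    hu_lesion_art = art,
    hu_lesion_del = del,
    hu_liver_art_1 = liver_art + d_art,
    hu_liver_art_2 = liver_art - d_art,
    hu_liver_del_1 = liver_del + d_del,
    hu_liver_del_2 = liver_del - d_del,
    margins = ifelse(lesions$smooth, "smooth", "other"),
    diameter_mm = lesions$diameter_mm,
    location = lesions$location,
    response = lesions$response
  )
  # randomize row order so cell blocks are not positional
  out <- out[sample.int(n), ]
  out$lesion_id <- sprintf("L%03d", seq_len(n))
  out$patient_id <- sprintf("P%03d", seq_len(n))
  attr(out, "generator") <- list(package = "washoutCT",
                                 version = as.character(utils::packageVersion("washoutCT")),
                                 seed = seed, mode = mode)
  out
}

#' Simulate a second blinded reader
#'
#' Perturbs a lesion table to emulate independent re-measurement: Gaussian
#' noise with standard deviation `hu_sd` is added independently to every HU
#' measurement (lesion UE/ART/DEL and each of the four liver ROI means), and
#' the margins call is flipped with probability `margin_flip_prob`. Zero
#' jitter returns the input unchanged.
#'
#' @param data Lesion table (as from [generate_cohort()]).
#' @param hu_sd Measurement noise SD in HU (>= 0).
#' @param margin_flip_prob Probability of discordant margins call (in \[0, 1\]).
#' @param preset `"calibrated"` sets jitter magnitudes tuned so downstream
#'   agreement lands near published inter-reader levels (ICC about 0.8 for
#'   DPAR, kappa about 0.76 for margins); `"none"` is the identity.
#' @param seed Optional integer seed.
#' @return The perturbed lesion table (tibble).
#' @export
jitter_reader <- function(data, hu_sd = 0, margin_flip_prob = 0,
                          preset = NULL, seed = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("calibrated", "none"))
    if (preset == "calibrated") {
      hu_sd <- 6.5
      margin_flip_prob <- 0.115
    } else {
      hu_sd <- 0; margin_flip_prob <- 0
    }
  }
  if (hu_sd < 0 || margin_flip_prob < 0 || margin_flip_prob > 1) {
    stop("jitter parameters must be >= 0 (flip probability <= 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  data <- tibble::as_tibble(data)
  hu_cols <- intersect(
    c("hu_lesion_ue", "hu_lesion_art", "hu_lesion_del",
      "hu_liver_art_1", "hu_liver_art_2", "hu_liver_del_1", "hu_liver_del_2",
      "hu_liver_art", "hu_liver_del"),
    names(data)
  )
  if (hu_sd > 0) {
    for (col in hu_cols) data[[col]] <- data[[col]] + rnorm(nrow(data), 0, hu_sd)
  }
  if (margin_flip_prob > 0 && "margins" %in% names(data)) {
    flip <- runif(nrow(data)) < margin_flip_prob
    data$margins[flip] <- ifelse(data$margins[flip] == "smooth", "other", "smooth")
  }
  data
}
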