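roc_of <- function(scores, is_pos) {
  roc_auc(tibble::tibble(s = scores, y = is_pos), s, y)
}

test_that("AUC equals the pair-enumeration oracle and handles edge cases", {
  set.seed(14)
  for (i in 1:15) {
    n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
    scores <- c(sample(1:10, n1, replace = TRUE), sample(1:10, n0, replace = TRUE))
    is_pos <- rep(c(TRUE, FALSE), c(n1, n0))
    expect_equal(roc_of(scores, is_pos)$auc, oracle_auc(scores, is_pos),
                 tolerance = 1e-12)
  }
  # perfect separation and constant score
  expect_equal(roc_of(c(5, 6, 7, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))$auc, 1.0)
  expect_equal(roc_of(rep(2, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)
  expect_error(roc_of(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("AUC equals the scaled Mann-Whitney U on shared data", {
  set.seed(15)
  for (i in 1:10) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    x1 <- round(rnorm(n1, 1, 2), 1); x0 <- round(rnorm(n0, 0, 2), 1)
    auc <- roc_of(c(x1, x0), rep(c(TRUE, FALSE), c(n1, n0)))$auc
    u <- mann_whitney_u(x1, x0)$u
    expect_equal(auc, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("ROC curve is monotone with both endpoints and matches pROC AUC", {
  set.seed(16)
  scores <- c(rnorm(40, 1), rnorm(40))
  is_pos <- rep(c(TRUE, FALSE), each = 40)
  r <- roc_of(scores, is_pos)
  expect_true(all(diff(r$curve$sensitivity) >= 0)) # threshold descending order
  expect_true(all(diff(r$curve$specificity) <= 0))
  expect_equal(r$curve$sensitivity[c(1, nrow(r$curve))], c(0, 1))
  expect_equal(r$curve$specificity[c(1, nrow(r$curve))], c(1, 0))

  skip_if_not_installed("pROC")
  pr <- pROC::roc(response = is_pos, predictor = scores, quiet = TRUE,
                  direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(r$conf_low, r$conf_high), ci[c(1, 3)], tolerance = 1e-9)
})

test_that("threshold criteria match the brute-force scan over distinct cuts", {
  set.seed(17)
  for (i in 1:15) {
    n1 <- sample(3:12, 1); n0 <- sample(3:12, 1)
    scores <- c(sample(seq(0, 5, 0.5), n1, replace = TRUE),
                sample(seq(0, 5, 0.5), n0, replace = TRUE))
    is_pos <- rep(c(TRUE, FALSE), c(n1, n0))
    if (length(unique(is_pos)) < 2) next
    sel <- select_threshold(roc_of(scores, is_pos))
    want <- oracle_threshold_cuts(scores, is_pos)
    expect_equal(sel$cut_youden, want[["youden"]])
    expect_equal(sel$cut_harmonic_mean, want[["hmean"]])
    expect_equal(sel$cut_corner_distance, want[["corner"]])
  }
})

test_that("perfectly separated scores give the gap midpoint under all criteria", {
  sel <- select_threshold(roc_of(c(10, 11, 12, 1, 2, 3),
                                 rep(c(TRUE, FALSE), each = 3)))
  expect_true(sel$agreement)
  expect_equal(sel$consensus, (3 + 10) / 2)
  expect_equal(sel$by_youden, 6.5)
  expect_equal(sel$by_harmonic_mean, 6.5)
  expect_equal(sel$by_corner_distance, 6.5)
})

test_that("the synthetic reference cohort yields a consensus threshold near 120", {
  cohort <- add_enhancement_indices(generate_cohort())
  cohort$cr <- dichotomize_response(cohort$response)
  r <- roc_auc(cohort, dpar, cr)
  sel <- select_threshold(r)
  expect_gte(sel$consensus, 115)
  expect_lte(sel$consensus, 125)
  # discrimination is real but quartile calibration does not pin the AUC
  expect_gt(r$auc, 0.5)
})
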