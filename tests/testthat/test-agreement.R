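test_that("signed-rank test matches exact sign-assignment enumeration", {
  set.seed(25)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    d <- round(rnorm(n, 0.3, 1), 2)
    d <- d[d != 0]
    if (anyDuplicated(abs(d)) > 0 || length(d) < 3) next
    r1 <- cumsum(abs(d)) + 10
    r2 <- r1 - d
    expect_equal(wilcoxon_signed_rank(r1, r2)$p_value, oracle_signed_rank_p(d),
                 tolerance = 1e-10)
  }
})

test_that("signed-rank degenerate and extreme cases behave", {
  x <- c(100, 110, 120, 130, 140)
  expect_warning(r <- wilcoxon_signed_rank(x, x), "no nonzero")
  expect_equal(r$p_value, 1)
  # constant shift: the smallest attainable two-sided p for n = 5 is 2/2^5
  shifted <- wilcoxon_signed_rank(x, x + c(1, 2, 3, 4, 5) * 0.01)
  expect_equal(shifted$p_value, 2 / 32, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(x, x[-1]), "same number")
})

test_that("ICC(2,1) matches the hand ANOVA decomposition on a worked set", {
  r1 <- c(100, 105, 112, 120, 130)
  r2 <- c(102, 104, 115, 119, 133)
  # hand mean-squares computation
  x <- cbind(r1, r2); n <- 5; k <- 2
  msr <- k * var(rowMeans(x))
  msc <- n * var(colMeans(x))
  resid <- x - outer(rowMeans(x), c(1, 1)) - outer(rep(1, n), colMeans(x)) + mean(x)
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  want <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc(r1, r2)$icc, want, tolerance = 1e-12)

  expect_equal(icc(r1, r1)$icc, 1.0)
  expect_warning(icc(rep(5, 4), rep(5, 4)), "degenerate")
})

test_that("ICC is symmetric and invariant under a common affine transform", {
  set.seed(26)
  r1 <- rnorm(30, 120, 15); r2 <- r1 + rnorm(30, 0, 6)
  expect_equal(icc(r1, r2)$icc, icc(r2, r1)$icc, tolerance = 1e-12)
  expect_equal(icc(2.5 * r1 - 40, 2.5 * r2 - 40)$icc, icc(r1, r2)$icc,
               tolerance = 1e-9)
})

test_that("two-rater Cronbach alpha matches the hand variance computation", {
  r1 <- c(10, 12, 15, 11, 14)
  r2 <- c(11, 12, 14, 12, 15)
  want <- 2 * (1 - (var(r1) + var(r2)) / var(r1 + r2))
  expect_equal(cronbach_coefficient(r1, r2)$alpha, want, tolerance = 1e-12)
  expect_equal(cronbach_coefficient(r1, r1)$alpha, 1.0)

  # independent readings: alpha ~ 0 at large n
  set.seed(27)
  a <- rnorm(5000); b <- rnorm(5000)
  expect_lt(abs(cronbach_coefficient(a, b)$alpha), 0.1)
})

test_that("Cohen kappa matches hand computation and its bounds", {
  r1 <- rep(c("smooth", "other"), c(25, 25))
  r2 <- rep(c("smooth", "other", "smooth", "other"), c(20, 5, 5, 20))
  k <- cohen_kappa(r1, r2)
  expect_equal(k$kappa, 0.6) # p_o = 0.8, p_e = 0.5
  expect_equal(cohen_kappa(r1, r1)$kappa, 1.0)
  expect_equal(cohen_kappa(r1, r2)$kappa, cohen_kappa(r2, r1)$kappa)
  # kappa <= p_o whenever p_e > 0
  expect_lte(k$kappa, k$p_observed)
  expect_warning(cohen_kappa(rep("smooth", 5), rep("smooth", 5)), "degenerate")
})

test_that("zero jitter gives perfect agreement; calibrated jitter lands in the published bands", {
  cohort <- generate_cohort()
  same <- jitter_reader(cohort, preset = "none")
  # identical readers: the matched-pairs test warns (p = 1), agreement is perfect
  tab <- suppressWarnings(agreement_table(cohort, same))
  expect_equal(tab$icc[tab$variable == "dpar"], 1.0)
  expect_equal(tab$kappa[tab$variable == "margins"], 1.0)

  # calibrated preset: average over seeded replicates near ICC 0.8 / kappa 0.76
  reps <- lapply(1:12, function(i) {
    r2 <- jitter_reader(cohort, preset = "calibrated", seed = 100 + i)
    tab <- agreement_table(cohort, r2, variables = "dpar")
    c(icc = tab$icc[1], kappa = tab$kappa[2])
  })
  m <- colMeans(do.call(rbind, reps))
  expect_gt(m[["icc"]], 0.65); expect_lt(m[["icc"]], 0.92)
  expect_gt(m[["kappa"]], 0.6); expect_lt(m[["kappa"]], 0.9)

  # monotonicity: extreme jitter strictly degrades agreement
  extreme <- mean(sapply(1:6, function(i) {
    r2 <- jitter_reader(cohort, hu_sd = 65, seed = 200 + i)
    agreement_table(cohort, r2, variables = "dpar", margins = FALSE)$icc[1]
  }))
  expect_lt(extreme, m[["icc"]])
})
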