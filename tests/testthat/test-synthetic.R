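test_that("DPAR sampler hits its population quartiles and threshold exceedance", {
  # population values read off the quantile function directly
  s_plus <- washoutCT:::dpar_sampler("CR+")
  expect_equal(s_plus$Q(c(0.25, 0.5, 0.75)), c(116, 124, 139))
  expect_equal(1 - s_plus$F(120), 41 / 64, tolerance = 1e-12)

  s_minus <- washoutCT:::dpar_sampler("CR-")
  expect_equal(s_minus$Q(c(0.25, 0.5, 0.75)), c(108, 115, 123))
  expect_equal(1 - s_minus$F(120), 21 / 65, tolerance = 1e-12)

  # large-sample empirical check of the draws themselves
  x <- sample_dpar(2e5, "CR+", seed = 4)
  expect_equal(unname(quantile(x, c(0.25, 0.5, 0.75))), c(116, 124, 139),
               tolerance = 0.01)
  expect_equal(mean(x >= 120), 41 / 64, tolerance = 0.01)
  expect_error(sample_dpar(0, "CR+"), ">= 1")
})

test_that("sample medians of CR+ draws center on the published group median", {
  meds <- vapply(1:300, function(i) median(sample_dpar(64, "CR+", seed = i)),
                 numeric(1))
  expect_equal(median(meds), 124, tolerance = 0.5)
})

test_that("truncated draws respect the threshold side and are seed-reproducible", {
  hi <- sample_dpar(500, "CR-", seed = 8, side = "high")
  lo <- sample_dpar(500, "CR+", seed = 8, side = "low")
  expect_true(all(hi >= 120))
  expect_true(all(lo < 120))
  expect_identical(sample_dpar(50, "CR+", seed = 99), sample_dpar(50, "CR+", seed = 99))
})

test_that("exact-counts cohort reproduces the calibrated joint structure verbatim", {
  cohort <- add_enhancement_indices(generate_cohort(seed = 20160101))
  expect_equal(nrow(cohort), 129L)
  expect_equal(sum(cohort$response == "CR"), 64L)
  expect_equal(as.integer(table(factor(cohort$response, c("CR", "PR", "SD", "PD")))),
               c(64L, 53L, 7L, 5L))
  expect_equal(sum(cohort$dpar >= 120), 62L)
  expect_equal(sum(cohort$margins == "smooth"), 58L)

  cells <- dplyr::count(cohort, high = dpar >= 120, smooth = margins == "smooth",
                        cr = response == "CR")
  get <- function(h, s, c_) cells$n[cells$high == h & cells$smooth == s & cells$cr == c_]
  expect_equal(get(TRUE, TRUE, TRUE), 26L)
  expect_equal(get(TRUE, FALSE, TRUE), 15L)
  expect_equal(get(FALSE, TRUE, TRUE), 12L)
  expect_equal(get(FALSE, FALSE, TRUE), 11L)

  # every DPAR on the correct side of 120 for its cell is implied by the cell
  # counts above plus the threshold-side totals
  expect_error(generate_cohort(n_lesions = 100, mode = "exact_counts"),
               "exact_counts mode requires")
})

test_that("exact-counts cohort group DPAR medians sit near the calibration quartiles", {
  cohort <- add_enhancement_indices(generate_cohort(seed = 20160101))
  cr <- dichotomize_response(cohort$response) == "CR+"
  expect_equal(median(cohort$dpar[cr]), 124, tolerance = 5)
  expect_equal(median(cohort$dpar[!cr]), 115, tolerance = 5)
})

test_that("generated HU profiles are internally consistent and indices recoverable", {
  cohort <- generate_cohort(seed = 7, mode = "sampled", n_lesions = 60)
  idx <- add_enhancement_indices(cohort)
  # liver pair averages reproduce the reference used to build the profile
  expect_equal(liver_reference(cohort$hu_liver_art_1, cohort$hu_liver_art_2),
               idx$hu_liver_art, tolerance = 1e-12)
  expect_true(all(idx$dpar > 0))
  expect_true(all(is.finite(idx$cer)))
})

test_that("sampled mode reproduces cell proportions in expectation", {
  n <- 2000
  cohort <- add_enhancement_indices(generate_cohort(n, mode = "sampled", seed = 31))
  p_hat <- c(
    mean(cohort$dpar >= 120 & cohort$margins == "smooth"),
    mean(cohort$dpar >= 120 & cohort$margins != "smooth"),
    mean(cohort$dpar < 120 & cohort$margins == "smooth"),
    mean(cohort$dpar < 120 & cohort$margins != "smooth")
  )
  p <- c(33, 29, 25, 42) / 129
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(p_hat - p) < 3 * se))
  expect_error(generate_cohort(5, mode = "sampled"), ">= 8")
})

test_that("phase dispersion ordering MAD(ART) > MAD(DEL) > MAD(UE) holds", {
  for (seed in c(20160101, 1, 2)) {
    cohort <- generate_cohort(seed = seed)
    m_ue <- mad_unscaled(cohort$hu_lesion_ue)
    m_art <- mad_unscaled(cohort$hu_lesion_art)
    m_del <- mad_unscaled(cohort$hu_lesion_del)
    expect_gt(m_art, m_del)
    expect_gt(m_del, m_ue)
  }
})

test_that("generation is bit-reproducible from the seed and rejects bad calibration", {
  a <- generate_cohort(seed = 123)
  b <- generate_cohort(seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))

  cal <- default_calibration()
  cal$dpar$`CR+`$quartiles <- c(124, 116, 139)
  expect_error(generate_cohort(calibration = cal), "monotone")
})
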