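fig2 <- list(cer = 109.4, llc = 56.3, wo_abs = 46.5, wo_rel = 24.3, dpar = 123.2)

test_that("reconstructed reference profile forward-computes to the printed indices", {
  p <- reconstruct_profile(cer = fig2$cer, llc = fig2$llc, wo_rel = fig2$wo_rel,
                           dpar = fig2$dpar, ue_anchor = 50)
  expect_equal(p$hu_lesion_art, 104.7, tolerance = 0.05)
  expect_equal(round(p$hu_lesion_del, 1), 79.3)
  expect_equal(p$hu_liver_del, 97.65, tolerance = 1e-3)

  idx <- enhancement_indices(p$hu_lesion_ue, p$hu_lesion_art, p$hu_lesion_del,
                             p$hu_liver_art, p$hu_liver_del)
  expect_equal(round(idx$cer, 1), fig2$cer)
  expect_equal(round(idx$llc, 1), fig2$llc)
  expect_equal(round(idx$wo_abs, 1), fig2$wo_abs)
  expect_equal(round(idx$wo_rel, 1), fig2$wo_rel)
  expect_equal(round(idx$dpar, 1), fig2$dpar)
})

test_that("degenerate profiles give identity index values and NA wash-out", {
  # no enhancement: ART = UE, DEL = ART, LIVDEL = DEL
  idx <- enhancement_indices(80, 80, 80, 80, 80)
  expect_equal(idx$cer, 0)
  expect_equal(idx$wo_rel, 0)
  expect_equal(idx$dpar, 100)
  expect_true(is.na(idx$wo_abs)) # denominator ART - UE = 0

  # isoattenuating lesion in arterial phase
  expect_equal(enhancement_indices(50, 100, 80, 100, 90)$llc, 0)
})

test_that("indices are scale-invariant and flag non-positive denominators", {
  set.seed(7)
  for (i in 1:20) {
    ue <- runif(1, 30, 70); art <- runif(1, 80, 200); del <- runif(1, 60, 150)
    la <- runif(1, 60, 120); ld <- runif(1, 70, 130)
    base <- enhancement_indices(ue, art, del, la, ld)
    k <- runif(1, 0.1, 10)
    scaled <- enhancement_indices(k * ue, k * art, k * del, k * la, k * ld)
    expect_equal(unname(unlist(base)), unname(unlist(scaled)), tolerance = 1e-9)
  }
  # negative / zero denominators -> NA, not error
  idx <- suppressWarnings(enhancement_indices(-5, 100, 80, 90, 95))
  expect_true(is.na(idx$cer))
  expect_false(is.na(idx$llc))
  expect_warning(enhancement_indices(-5, -6, -1, -2, 4), "no evaluable index")
})

test_that("wo_abs identity holds exactly for computed indices and printed values", {
  expect_equal(round(wo_abs_from_identity(109.4, 24.3), 1), 46.5)
  expect_equal(wo_abs_from_identity(100, 10), 20)
  expect_equal(wo_abs_from_identity(57.3, 0), 0)
  expect_true(is.na(wo_abs_from_identity(-3, 10)))

  set.seed(11)
  for (i in 1:20) {
    ue <- runif(1, 30, 70); art <- ue + runif(1, 5, 150); del <- runif(1, 40, art)
    idx <- enhancement_indices(ue, art, del, runif(1, 60, 120), runif(1, 70, 130))
    expect_equal(idx$wo_abs, wo_abs_from_identity(idx$cer, idx$wo_rel),
                 tolerance = 1e-9)
  }
})

test_that("profile round-trip is the identity to 1e-9", {
  set.seed(3)
  for (i in 1:20) {
    ue <- runif(1, 30, 70); art <- ue + runif(1, 5, 150); del <- runif(1, 40, art)
    la <- runif(1, 60, 120); ld <- runif(1, 70, 130)
    idx <- enhancement_indices(ue, art, del, la, ld)
    back <- reconstruct_profile(cer = idx$cer, llc = idx$llc, wo_rel = idx$wo_rel,
                                dpar = idx$dpar, ue_anchor = ue)
    expect_equal(unname(unlist(back)), c(ue, art, del, la, ld), tolerance = 1e-9)
    # and index vectors round-trip through the reconstruction
    idx2 <- enhancement_indices(back$hu_lesion_ue, back$hu_lesion_art,
                                back$hu_lesion_del, back$hu_liver_art,
                                back$hu_liver_del)
    expect_equal(unname(unlist(idx2)), unname(unlist(idx)), tolerance = 1e-9)
  }
})

test_that("inconsistent wo_abs triples are warned about with the residual", {
  # second worked example: implied wo_abs ~1.8 vs printed 1.7, within 0.15 band
  expect_silent(reconstruct_profile(cer = 123.4, llc = 17.4, wo_rel = 1,
                                    dpar = 102.9, ue_anchor = 50, wo_abs = 1.7))
  implied <- wo_abs_from_identity(123.4, 1)
  expect_lt(abs(implied - 1.7), 0.15)
  expect_warning(
    reconstruct_profile(cer = 100, llc = 50, wo_rel = 10, dpar = 110,
                        ue_anchor = 50, wo_abs = 25),
    "inconsistent"
  )
})

test_that("DPAR dichotomization is inclusive at the threshold and tracks liver contrast", {
  expect_equal(as.character(dichotomize_dpar(c(123.2, 120, 102.9, NA))),
               c("high", "high", "low", NA))
  # DPAR > 100 iff liver delayed > lesion delayed
  set.seed(5)
  for (i in 1:20) {
    del <- runif(1, 40, 120); ld <- runif(1, 40, 120)
    idx <- enhancement_indices(50, 150, del, 100, ld)
    expect_equal(idx$dpar > 100, ld > del)
  }
})

test_that("mRECIST dichotomization maps CR vs all others", {
  expect_equal(as.character(dichotomize_response(c("CR", "PR", "SD", "PD"))),
               c("CR+", "CR-", "CR-", "CR-"))
  mix <- rep(c("CR", "PR", "SD", "PD"), c(64, 53, 7, 5))
  expect_equal(as.integer(table(dichotomize_response(mix))), c(64L, 65L))
  expect_error(dichotomize_response("CRX"), "unknown mRECIST")
})
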