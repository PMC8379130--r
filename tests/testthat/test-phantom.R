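fig2_idx <- list(cer = 109.4, llc = 56.3, wo_rel = 24.3, dpar = 123.2)

test_that("noise-free phantom reproduces the requested indices through the full chain", {
  ph <- generate_phantom_series(cer = fig2_idx$cer, llc = fig2_idx$llc,
                                wo_rel = fig2_idx$wo_rel, dpar = fig2_idx$dpar)
  prof <- extract_profile(ph)
  idx <- enhancement_indices(prof$hu_lesion_ue, prof$hu_lesion_art,
                             prof$hu_lesion_del, prof$hu_liver_art,
                             prof$hu_liver_del)
  expect_equal(round(idx$cer, 1), 109.4)
  expect_equal(round(idx$llc, 1), 56.3)
  expect_equal(round(idx$wo_abs, 1), 46.5)
  expect_equal(round(idx$wo_rel, 1), 24.3)
  expect_equal(round(idx$dpar, 1), 123.2)
  # roi_mean recovers true HU exactly at sigma = 0
  expect_equal(prof$hu_lesion_art, ph$truth$hu$hu_lesion_art, tolerance = 1e-12)
})

test_that("lesion identical to liver gives LLC 0 and DPAR 100", {
  # indices that make lesion == liver in every phase (liver UE matches anchor)
  ph <- generate_phantom_series(cer = 50, llc = 0, wo_rel = 10, dpar = 100,
                                liver_ue = 50, ue_anchor = 50)
  prof <- extract_profile(ph)
  idx <- enhancement_indices(prof$hu_lesion_ue, prof$hu_lesion_art,
                             prof$hu_lesion_del, prof$hu_liver_art,
                             prof$hu_liver_del)
  expect_equal(idx$llc, 0, tolerance = 1e-12)
  expect_equal(idx$dpar, 100, tolerance = 1e-12)
})

test_that("noisy replicate series estimate DPAR within Monte-Carlo error", {
  n_rep <- 120
  vals <- vapply(seq_len(n_rep), function(i) {
    ph <- generate_phantom_series(cer = 109.4, llc = 56.3, wo_rel = 24.3,
                                  dpar = 123.2, size = 64L,
                                  lesion_axes = c(9, 8),
                                  noise_sigma = c(10, 10, 10), seed = 500 + i)
    prof <- extract_profile(ph)
    enhancement_indices(prof$hu_lesion_ue, prof$hu_lesion_art,
                        prof$hu_lesion_del, prof$hu_liver_art,
                        prof$hu_liver_del)$dpar
  }, numeric(1))
  se <- stats::sd(vals) / sqrt(n_rep)
  expect_lt(abs(mean(vals) - 123.2), 3 * se + 0.2)
})

test_that("phantom geometry violations error", {
  expect_error(generate_phantom_series(cer = 100, llc = 50, wo_rel = 20,
                                       dpar = 110, size = 32L,
                                       lesion_axes = c(20, 20)),
               "larger than image")
})

test_that("phantom series round-trips through TIFF with the truth sidecar", {
  skip_if_not_installed("tiff")
  ph <- generate_phantom_series(cer = 109.4, llc = 56.3, wo_rel = 24.3,
                                dpar = 123.2, size = 48L, lesion_axes = c(7, 6))
  path <- file.path(withr::local_tempdir(), "series1")
  files <- write_phantom_series(ph, path, format = "tiff")
  expect_true(all(file.exists(files)))

  back <- read_phantom_series(path)
  # 16-bit quantization: recovery within 1 HU
  expect_equal(back$images$ART, ph$images$ART, tolerance = 1)
  prof <- extract_profile(back)
  expect_equal(round(enhancement_indices(prof$hu_lesion_ue, prof$hu_lesion_art,
                                         prof$hu_lesion_del, prof$hu_liver_art,
                                         prof$hu_liver_del)$dpar, 0), 123)
})
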