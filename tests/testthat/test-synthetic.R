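test_that("the generator is deterministic and annotates every seizure", {
  spec <- synthetic_spec(n_channels = 2, duration_s = 600,
                         seizure_onsets_s = c(300, 500), sop_min = 1,
                         seed = 23)
  a <- generate_patient(spec)
  b <- generate_patient(spec)
  expect_identical(a$recording$signals, b$recording$signals)
  expect_equal(nrow(a$recording$annotations), 2)
  expect_equal(a$recording$annotations$onset_s, c(300, 500))
  expect_true(all(c("shifted_channels", "seed") %in% names(a$manifest)))

  c2 <- generate_patient(synthetic_spec(n_channels = 2, duration_s = 600,
                                        seizure_onsets_s = c(300, 500),
                                        sop_min = 1, seed = 24))
  expect_false(identical(a$recording$signals, c2$recording$signals))
})

test_that("the generator specification rejects infeasible parameters", {
  expect_error(synthetic_spec(modulation_depth = 1.5))
  expect_error(synthetic_spec(fast_band_hz = c(40, 130), fs = 256), "Nyquist")
  expect_error(synthetic_spec(seizure_onsets_s = c(100, 200),
                              duration_s = 12 * 3600, sop_min = 60),
               "preictal window")
  expect_error(synthetic_spec(seizure_onsets_s = c(7200, 7200 + 600),
                              duration_s = 12 * 3600), "1.5 hours")
})

test_that("a planted coupling phase is recovered from a single channel", {
  spec <- synthetic_spec(n_channels = 1, duration_s = 300,
                         seizure_onsets_s = numeric(0), seed = 42)
  for (sd in c(42, 43)) {
    spec$seed <- sd
    x <- generate_coupled_signal(spec, channel = 1, coupling_phase = 0.24)
    rec <- recording(matrix(x, 1), spec$fs)
    pm <- coupling_phase_map(rec, band_pair("delta", "LG", spec$fs))
    expect_lt(max(abs(circ_diff(pm$phi_c, 0.24))), 0.15)
  }
})

test_that("without modulation the extractor finds no coupling", {
  spec0 <- synthetic_spec(n_channels = 1, duration_s = 300,
                          modulation_depth = 0,
                          seizure_onsets_s = numeric(0), seed = 42)
  spec8 <- spec0; spec8$modulation_depth <- 0.8
  c0 <- mean(coupling_phase_map(generate_patient(spec0)$recording,
                                band_pair("delta", "LG", 256))$concentration)
  c8 <- mean(coupling_phase_map(generate_patient(spec8)$recording,
                                band_pair("delta", "LG", 256))$concentration)
  expect_lt(c0, c8)
  expect_lt(c0, 0.15)
})

test_that("preictal windows shift the planted fraction of channels", {
  spec <- synthetic_spec(n_channels = 8, duration_s = 2 * 3600,
                         interictal_phase = 0.81, preictal_phase = -2.5,
                         preictal_fraction = 0.5, sop_min = 30,
                         seizure_onsets_s = 1.5 * 3600, seed = 31)
  pat <- generate_patient(spec)
  expect_length(pat$manifest$shifted_channels, 4)
  pm <- coupling_phase_map(pat$recording, band_pair("delta", "LG", 256))
  pre_win <- which(pm$window_times_s >= 3600 & pm$window_times_s < 1.5 * 3600)
  int_win <- which(pm$window_times_s < 3600)
  shifted <- pm$channel_labels %in% pat$manifest$shifted_channels
  # shifted channels sit near the preictal phase in preictal windows only
  expect_lt(max(abs(circ_diff(pm$phi_c[shifted, pre_win], -2.5))), 0.3)
  expect_lt(max(abs(circ_diff(pm$phi_c[shifted, int_win], 0.81))), 0.3)
  expect_lt(max(abs(circ_diff(pm$phi_c[!shifted, pre_win], 0.81))), 0.3)
})
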