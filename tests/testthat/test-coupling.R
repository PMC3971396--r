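test_that("band pair definitions follow the sampling rate", {
  p <- band_pair("delta", "HG", 1024)
  expect_equal(p$low_hz, c(0.5, 3))
  expect_equal(p$high_hz, c(70, 140))
  expect_equal(band_pair("delta", "HG", 256)$high_hz, c(70, 120))
  expect_equal(band_pair("theta", "LG", 400)$code, "LT")
  expect_length(band_pair_grid(512), 4)
})

test_that("phase-amplitude histogram bins and conserves samples", {
  set.seed(1)
  ph <- runif(5000, -pi, pi)
  h <- phase_amplitude_histogram(ph, rep(1, 5000))
  expect_equal(sum(h$counts), 5000)
  expect_equal(h$mean_amplitude[!h$empty],
               rep(1, sum(!h$empty)))

  # amplitude 1 + cos(phase): bin means match the bin-center values up to
  # bin discretization
  ph2 <- seq(-pi + 1e-6, pi, length.out = 40000)
  h2 <- phase_amplitude_histogram(ph2, 1 + cos(ph2))
  expect_lt(max(abs(h2$mean_amplitude - (1 + cos(h2$bin_centers)))), 0.01)

  # a bin never visited is flagged empty
  ph3 <- ph[ph < h$bin_edges[7] | ph >= h$bin_edges[8]]
  h3 <- phase_amplitude_histogram(ph3, rep(1, length(ph3)))
  expect_equal(h3$counts[7], 0)
  expect_true(h3$empty[7])

  expect_error(phase_amplitude_histogram(1:3, 1:4), "equal length")
})

test_that("mean coupling phase is the amplitude-weighted circular mean", {
  # all amplitude in a single bin
  h <- phase_amplitude_histogram(rep(-2.62, 100), rep(3, 100))
  m <- mean_coupling_phase(h)
  ctr <- h$bin_centers[which(h$counts > 0)]
  expect_equal(m$phi_c, ctr)
  expect_equal(m$concentration, 1)

  # von-Mises-like bin profile centred at 1.0
  ph <- seq(-pi + 1e-6, pi, length.out = 50000)
  h2 <- phase_amplitude_histogram(ph, 1 + 0.5 * cos(ph - 1.0))
  m2 <- mean_coupling_phase(h2)
  expect_lt(abs(m2$phi_c - 1.0), pi / 40)
  expect_gt(m2$concentration, 0)

  # flat distribution: no preferred phase
  h3 <- phase_amplitude_histogram(ph, rep(2, length(ph)))
  expect_lt(mean_coupling_phase(h3)$concentration, 1e-6)

  h4 <- h3; h4$counts[] <- 0L; h4$empty[] <- TRUE
  expect_error(mean_coupling_phase(h4), "empty")
})

test_that("histogram route matches a brute-force weighted circular mean", {
  set.seed(7)
  for (rep in 1:5) {
    ph <- runif(20000, -pi, pi)
    am <- pmax(0, 1 + 0.7 * cos(ph - 0.5) + rnorm(20000, sd = 0.2))
    got <- mean_coupling_phase(phase_amplitude_histogram(ph, am))
    want <- Arg(sum(am * exp(1i * ph)) / sum(am))
    expect_lt(abs(atan2(sin(got$phi_c - want), cos(got$phi_c - want))),
              2 * pi / 40 / 2)     # half a bin width
  }
})

test_that("phase offsets rotate the coupling phase and keep concentration", {
  set.seed(8)
  ph <- runif(30000, -pi, pi)
  am <- pmax(0, 1 + 0.8 * cos(ph - 0.3))
  base <- mean_coupling_phase(phase_amplitude_histogram(ph, am))
  for (theta in c(0.5, -1.2, 2.9)) {
    ph2 <- ((ph + theta + pi) %% (2 * pi)) - pi
    rot <- mean_coupling_phase(phase_amplitude_histogram(ph2, am))
    expect_lt(abs(circ_diff(rot$phi_c, base$phi_c + theta)), 2 * pi / 40)
    expect_equal(rot$concentration, base$concentration, tolerance = 0.02)
  }
})

test_that("planted per-channel coupling phases are recovered in every window", {
  rec <- small_coupled_recording()
  pm <- coupling_phase_map(rec, band_pair("delta", "LG", rec$fs))
  expect_equal(dim(pm$phi_c), c(3, 5))
  planted <- c(0, 1, -2)
  for (ch in 1:3) {
    expect_lt(max(abs(circ_diff(pm$phi_c[ch, ], planted[ch]))), 0.15)
  }
})

test_that("concentration grows with modulation depth on a fixed seed", {
  conc <- vapply(c(0, 0.4, 0.8), function(depth) {
    spec <- synthetic_spec(n_channels = 1, duration_s = 180,
                           interictal_phase = 0.5, modulation_depth = depth,
                           seizure_onsets_s = numeric(0), seed = 55)
    rec <- generate_patient(spec)$recording
    pm <- coupling_phase_map(rec, band_pair("delta", "LG", rec$fs))
    mean(pm$concentration)
  }, 0)
  expect_true(all(diff(conc) > 0))
  expect_lt(conc[1], 0.15)     # no planted coupling: concentration near 0
})

test_that("window bookkeeping truncates trailing partial windows", {
  spec <- synthetic_spec(n_channels = 1, duration_s = 659,
                         seizure_onsets_s = numeric(0), seed = 9)
  rec <- generate_patient(spec)$recording
  pm <- coupling_phase_map(rec, band_pair("delta", "LG", rec$fs))
  expect_equal(ncol(pm$phi_c), 10)
  expect_error(coupling_phase_map(
    recording(matrix(rnorm(256 * 30), 1), 256),
    band_pair("delta", "LG", 256)), "shorter")
})

test_that("spectral fast path agrees with the exact whole-record path", {
  spec <- synthetic_spec(n_channels = 2, duration_s = 420,
                         interictal_phase = c(0.8, -2.2),
                         seizure_onsets_s = numeric(0), seed = 77)
  rec <- generate_patient(spec)$recording
  for (pr in list(band_pair("delta", "LG", 256), band_pair("theta", "HG", 256))) {
    a <- coupling_phase_map(rec, pr, method = "spectral")
    b <- coupling_phase_map(rec, pr, method = "exact")
    expect_lt(max(abs(circ_diff(a$phi_c, b$phi_c))), 0.05)
    expect_lt(max(abs(a$concentration - b$concentration)), 0.05)
  }
})
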