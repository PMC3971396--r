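test_that("the 11-interval grid partitions the circle", {
  g <- phase_interval_grid()
  expect_equal(nrow(g), 11)
  expect_equal(g$hi - g$lo, rep(2 * pi / 11, 11))
  expect_equal(g$lo[1], -pi)
  expect_equal(g$hi[11], pi)
  expect_equal(g$lo[-1], g$hi[-11])
  # every phase lands in exactly one interval
  set.seed(3)
  ph <- c(runif(5000, -pi, pi), -pi, pi, g$lo[5])
  hits <- vapply(ph, function(p) {
    sum(p >= g$lo & (p < g$hi | (abs(g$hi - pi) < 1e-9 & p <= pi)))
  }, 0)
  expect_true(all(hits == 1))
})

test_that("reported per-patient preictal phases sit on the grid spacing", {
  tab <- load_patient_table()
  ctr <- sort(unique(tab$preictal_phase_rad))
  main <- ctr[ctr <= 2.52 + 1e-9]       # the ten regularly spaced centers
  expect_equal(diff(main), rep(2 * pi / 11, 9), tolerance = 0.02)
})

test_that("occupancy counts the contacts inside an interval", {
  g <- phase_interval_grid()
  phi <- matrix(g$center[4], 10, 6)
  map <- structure(list(phi_c = phi, concentration = phi * 0 + 1,
                        window_s = 60, window_times_s = (0:5) * 60,
                        channel_labels = sprintf("c%d", 1:10)),
                   class = "coupling_map")
  expect_equal(occupancy(map, g[4, ])$raw, rep(1, 6))
  expect_equal(occupancy(map, g[7, ])$raw, rep(0, 6))

  phi2 <- phi
  phi2[4:10, ] <- g$center[9]           # 3 of 10 contacts remain inside
  map$phi_c <- phi2
  expect_equal(occupancy(map, g[4, ])$raw, rep(0.3, 6))

  # undefined channels drop out of numerator and denominator
  phi2[1, ] <- NA
  map$phi_c <- phi2
  expect_equal(occupancy(map, g[4, ])$raw, rep(2 / 9, 6))
  phi2[] <- NA
  map$phi_c <- phi2
  expect_true(all(is.na(occupancy(map, g[4, ])$raw)))
})

test_that("occupancies over the grid sum to one when all phases are defined", {
  set.seed(11)
  map <- structure(list(phi_c = matrix(runif(160, -pi, pi), 16),
                        window_s = 60, window_times_s = (0:9) * 60,
                        channel_labels = sprintf("c%d", 1:16)),
                   class = "coupling_map")
  g <- phase_interval_grid()
  tot <- Reduce(`+`, lapply(seq_len(11), function(i) occupancy(map, g[i, ])$raw))
  expect_equal(tot, rep(1, 10))
})

test_that("the Kalman smoother tracks constants, reduces noise, and is causal-monotone", {
  # a constant observation stream is tracked exactly
  s0 <- kalman_smooth(rep(0.4, 100), q = 1e-4, r = 1e-2)
  expect_lt(abs(s0[100] - 0.4), 1e-6)
  # and an off-level start is forgotten geometrically
  x <- c(0, rep(1, 100))
  s <- kalman_smooth(x, q = 1e-4, r = 1e-2)
  expect_lt(abs(s[101] - 1), 1e-4)

  # variance reduction on i.i.d. noise about a constant
  set.seed(5)
  z <- 0.5 + rnorm(400, sd = 0.1)
  sz <- kalman_smooth(z)
  half <- 201:400
  expect_lt(var(sz[half]), var(z[half]))

  # monotone response to a step
  st <- kalman_smooth(c(rep(0, 20), rep(1, 50)))
  expect_true(all(diff(st[20:70]) >= 0))

  expect_error(kalman_smooth(c(0.1, Inf)), "finite")
  expect_error(kalman_smooth(0.5, q = 0), "q > 0")
})

test_that("alarms respect the threshold and refractory period", {
  al <- generate_alarms(c(0.1, 0.2, 0.9, 0.9, 0.9), 0.5, 600, 60)
  expect_equal(al$alarm_times, 120)

  expect_length(generate_alarms(rep(0.2, 50), 0.5, 600, 60)$alarm_times, 0)

  s <- rep(0, 60); s[c(10, 40)] <- 0.9       # separated by > refractory
  al2 <- generate_alarms(s, 0.5, 600, 60)
  expect_equal(al2$alarm_times, c(9, 39) * 60)
})

test_that("alarm spacing and threshold monotonicity hold on fuzzed series", {
  set.seed(21)
  for (i in 1:30) {
    s <- runif(300)
    refr <- sample(c(600, 1800, 3600), 1)
    thr <- runif(1, 0.2, 0.8)
    al <- generate_alarms(s, thr, refr, 60)
    if (length(al$alarm_times) > 1) {
      expect_gte(min(diff(al$alarm_times)), refr)
    }
    n_hi <- length(generate_alarms(s, min(thr + 0.1, 0.99), refr, 60)$alarm_times)
    expect_lte(n_hi, length(al$alarm_times))
  }
})

test_that("implicated contacts need twice their interictal incidence", {
  g <- phase_interval_grid()
  inside <- g$center[6]; outside <- g$center[1]
  mk_row <- function(pre_rate, inter_rate) {
    c(ifelse(seq_len(10) <= round(10 * inter_rate), inside, outside),
      ifelse(seq_len(10) <= round(10 * pre_rate), inside, outside))
  }
  phi <- rbind(mk_row(0.9, 0.3), mk_row(0.5, 0.5), mk_row(0.6, 0.3),
               mk_row(0.4, 0))
  map <- structure(list(phi_c = phi, window_s = 60,
                        window_times_s = (0:19) * 60,
                        channel_labels = c("A", "B", "C", "D")),
                   class = "coupling_map")
  imp <- identify_implicated_contacts(map, g[6, ],
                                      preictal_windows = 11:20,
                                      interictal_windows = 1:10)
  expect_true("A" %in% imp)       # 3x increase
  expect_false("B" %in% imp)      # unchanged
  expect_true("C" %in% imp)       # exactly 2x: inclusive boundary
  expect_true("D" %in% imp)       # from zero to positive
  expect_error(identify_implicated_contacts(map, g[6, ], integer(0), 1:10),
               "non-empty")
})
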