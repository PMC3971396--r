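# light stand-in carrying only annotations and duration, as accepted by
# split_train_test
fake_timeline <- function(onsets_h, dur_h) {
  structure(list(annotations = data.frame(onset_s = onsets_h * 3600,
                                          label = "sz"),
                 duration_s = dur_h * 3600),
            class = "coupling_map")
}

test_that("train span covers the first seizures plus preictal margin", {
  sp <- split_train_test(fake_timeline(c(5, 12, 20, 30, 50, 70, 80, 90), 100))
  expect_equal(sp$train, c(0, 31 * 3600))      # 4th onset + 60 min
  expect_equal(sp$test, c(31 * 3600, 100 * 3600))

  # the 10-hour floor dominates early seizures
  sp2 <- split_train_test(fake_timeline(c(1, 2.5, 4, 6, 20, 30), 40))
  expect_equal(sp2$train[2], 10 * 3600)

  expect_error(split_train_test(fake_timeline(c(5, 10, 15, 20), 40)),
               "unevaluable")
})

test_that("sensitivity and FPR follow the warning-time denominator rule", {
  # hand-computed example: 10-h span, seizure at 9 h, SOP 60 min,
  # false alarm at 2 h, true alarm at 8.5 h -> denominator 8 h
  perf <- score_alarms(c(2, 8.5) * 3600, 9 * 3600, 60, c(0, 10 * 3600))
  expect_equal(perf$ss, 1)
  expect_equal(perf$n_false_alarms, 1)
  expect_equal(perf$denominator_h, 8)
  expect_equal(perf$fpr, 0.125)

  none <- score_alarms(numeric(0), c(2, 6) * 3600, 60, c(0, 10 * 3600))
  expect_equal(none$ss, 0)
  expect_equal(none$fpr, 0)

  tight <- score_alarms(c(2, 6) * 3600 - 300, c(2, 6) * 3600, 60,
                        c(0, 10 * 3600))
  expect_equal(tight$ss, 1)
  expect_equal(tight$fpr, 0)
})

test_that("alarm scoring matches a brute-force timeline oracle", {
  expect_gt(score_oracle_check(200, seed = 31), 150)
})

test_that("random predictor criticals match binomial enumeration and limits", {
  expect_equal(random_predictor_sensitivity(0, 60, 5), 1 / 5)
  expect_equal(random_predictor_sensitivity(1000, 60, 8), 1)

  # exhaustive enumeration oracle at K = 10, FPR = 0.33/h, SOP = 60 min
  p1 <- 1 - exp(-0.33)
  tails <- vapply(1:10, function(k) {
    sum(vapply(k:10, function(j) choose(10, j) * p1^j * (1 - p1)^(10 - j), 0))
  }, 0)
  k_star <- which(tails < 0.01)[1]
  expect_equal(random_predictor_sensitivity(0.33, 60, 10), k_star / 10)

  # monotone in FPR and SOP
  fprs <- seq(0, 2, by = 0.25)
  s1 <- vapply(fprs, random_predictor_sensitivity, 0, sop_min = 30, K = 12)
  expect_true(all(diff(s1) >= 0))
  sops <- c(10, 30, 60)
  s2 <- vapply(sops, function(sp) random_predictor_sensitivity(0.4, sp, 12), 0)
  expect_true(all(diff(s2) >= 0))
})

test_that("group significance is a binomial upper tail with sane limits", {
  expect_equal(group_significance(0, 53, 0.05), 1)
  expect_equal(group_significance(1, 1, 0.05), 0.05)
  ps <- vapply(0:10, group_significance, 0, N = 30, alpha_patient = 0.05)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("the grid search selects a perfect configuration and breaks ties by FPR", {
  # craft maps so that exactly one (pair, interval) detects the seizure:
  # channels enter interval 6 only during the preictal hour
  g <- phase_interval_grid()
  n_win <- 720                                    # 12 h of 1-min windows
  onset_h <- 11
  pre <- (1:n_win - 1) >= (onset_h - 1) * 60 & (1:n_win - 1) < onset_h * 60
  phi <- matrix(g$center[2], 8, n_win)
  phi[, pre] <- g$center[6]
  mk_map <- function(phi, code) {
    structure(list(phi_c = phi, concentration = phi * 0 + 0.5,
                   pair = band_pair(switch(substr(code, 2, 2), D = "delta",
                                           T = "theta"),
                                    switch(substr(code, 1, 1), L = "LG",
                                           H = "HG"), 256),
                   window_s = 60, window_times_s = (1:n_win - 1) * 60,
                   channel_labels = sprintf("c%d", 1:8), fs = 256,
                   duration_s = n_win * 60,
                   annotations = data.frame(onset_s = onset_h * 3600,
                                            label = "sz")),
              class = "coupling_map")
  }
  flat <- matrix(g$center[2], 8, n_win)           # nothing to detect
  maps <- list(LD = mk_map(phi, "LD"), LT = mk_map(flat, "LT"),
               HD = mk_map(flat, "HD"), HT = mk_map(flat, "HT"))
  rec_stub <- structure(list(fs = 256,
                             annotations = maps$LD$annotations),
                        class = "eeg_recording")
  # score up to just past the onset so post-seizure smoother decay is not
  # penalized as a false warning
  opt <- optimize_parameters(rec_stub, train_span = c(0, onset_h * 3600 + 60),
                             maps = maps)
  expect_equal(opt$config$pair$code, "LD")
  expect_equal(opt$config$interval$center, g$center[6])
  expect_equal(opt$distance, 0)
  expect_equal(opt$train_performance$ss, 1)
  expect_equal(opt$train_performance$fpr, 0)

  # among equal distances the lower-FPR configuration wins
  s <- opt$search
  s$idx <- seq_len(nrow(s))
  best <- s[order(s$d, s$fpr, -s$ss, s$idx)[1], ]
  ties <- s[s$d == best$d, ]
  expect_true(all(best$fpr <= ties$fpr))
})
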