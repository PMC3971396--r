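# Shared fixtures, built in code and memoised across test files. The heavy
# reference patients (12 h, 16 channels) are expensive, so every file that
# needs one goes through this cache.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small interictal-only recording with per-channel planted phases
small_coupled_recording <- function() {
  memo("small_rec", {
    spec <- synthetic_spec(n_channels = 3, duration_s = 300,
                           interictal_phase = c(0, 1, -2),
                           seizure_onsets_s = numeric(0), seed = 101)
    generate_patient(spec)$recording
  })
}

# circular absolute difference
circ_diff <- function(a, b) atan2(sin(a - b), cos(a - b))

# index of the phase-grid interval containing a phase
grid_interval_of <- function(phi) {
  g <- phase_interval_grid()
  which(phi >= g$lo & phi < g$hi | (abs(g$hi - pi) < 1e-9 & phi == pi))
}

# Full prospective run on one 12-h reference patient; returns a light
# summary (no signals) plus the coupling maps for reuse.
run_reference_patient <- function(seed) {
  pat <- generate_patient(synthetic_spec(seed = seed))
  rec <- pat$recording
  maps <- coupling_phase_maps(rec)
  split <- split_train_test(rec)
  opt <- optimize_parameters(rec, split$train, maps = maps)
  test <- evaluate_detector(maps, opt$config, split$test)
  rm(rec, pat); gc(FALSE)
  list(seed = seed, config = opt$config,
       train_performance = opt$train_performance,
       test_performance = test$performance,
       split = split, maps = maps)
}

# Parameter-recovery study over the reference seeds; memoised so the
# end-to-end checks and module invariants share one run.
recovery_study <- function(seeds = 1:10) {
  memo("recovery", {
    spec0 <- synthetic_spec()
    planted_interval <- grid_interval_of(spec0$preictal_phase)
    runs <- lapply(seeds, run_reference_patient)
    hits <- vapply(runs, function(r) {
      r$config$pair$code == "LD" &&
        which(phase_interval_grid()$center == r$config$interval$center) ==
          planted_interval &&
        r$config$sop_min == spec0$sop_min
    }, TRUE)
    list(runs = runs, hits = hits, rate = mean(hits),
         planted_interval = planted_interval)
  })
}

# Brute-force timeline oracle for alarm scoring: marks every second of the
# span and classifies events by direct scan. Used to validate score_alarms
# on randomized instances.
score_oracle <- function(alarms, sz, sop_min, span) {
  sop <- sop_min * 60
  alarms <- alarms[alarms >= span[1] & alarms < span[2]]
  sz <- sz[sz >= span[1] & sz < span[2]]
  pred <- sum(vapply(sz, function(on) any(alarms >= on - sop & alarms < on),
                     TRUE))
  false_al <- alarms[vapply(alarms,
                            function(t) !any(sz > t & sz <= t + sop), TRUE)]
  sec <- span[1]:(span[2] - 1)
  blocked <- rep(FALSE, length(sec))
  for (on in sz) blocked[sec >= on - sop & sec < on] <- TRUE
  for (t in false_al) blocked[sec >= t & sec < t + sop] <- TRUE
  denom_h <- sum(!blocked) / 3600
  list(ss = if (length(sz)) pred / length(sz) else NA_real_,
       n_false = length(false_al), denom_h = denom_h,
       fpr = length(false_al) / denom_h)
}

# run `n` randomized comparisons; returns how many instances were checked
score_oracle_check <- function(n, seed) {
  set.seed(seed)
  n_checked <- 0
  for (i in seq_len(n)) {
    span <- c(0, sample(2:8, 1) * 3600)
    sop <- sample(c(10, 30, 60), 1)
    sz <- sort(sample(seq(sop * 60, span[2], by = 60), sample(0:5, 1)))
    alarms <- sort(sample(seq(0, span[2] - 1, by = 60), sample(0:20, 1)))
    want <- score_oracle(alarms, sz, sop, span)
    if (want$denom_h <= 0) next
    got <- score_alarms(alarms, sz, sop, span)
    expect_equal(got$ss, want$ss)
    expect_equal(got$n_false_alarms, want$n_false)
    expect_equal(got$denominator_h, want$denom_h, tolerance = 1e-9)
    expect_equal(got$fpr, want$fpr, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  n_checked
}

# Best sensitivity a band-power detector can reach without exceeding the
# coupling detector's false-prediction-rate budget: thresholds span the
# training-free quantile range up to the series maximum (so a silent,
# zero-FPR configuration always exists), and the matched set keeps those
# with FPR <= fpr_budget.
power_matched_ss <- function(band_series, rec, sop_min, span, fpr_budget) {
  vals <- band_series$values
  thr_grid <- unique(c(stats::quantile(vals, seq(0.5, 1, by = 0.002),
                                       na.rm = TRUE, names = FALSE)))
  perfs <- lapply(thr_grid, function(th) {
    if (th >= max(vals, na.rm = TRUE)) {
      return(list(ss = 0, fpr = 0))
    }
    al <- generate_alarms(vals, th, sop_min * 60, 5, band_series$times)
    tryCatch(score_alarms(al, rec$annotations$onset_s, sop_min, span),
             error = function(e) NULL)
  })
  perfs <- perfs[!vapply(perfs, is.null, TRUE)]
  fprs <- vapply(perfs, `[[`, 0, "fpr")
  ssb <- vapply(perfs, `[[`, 0, "ss")
  ok <- fprs <= fpr_budget + 1e-12
  if (!any(ok)) return(0)
  max(ssb[ok])
}
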