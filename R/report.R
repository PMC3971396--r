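#' Packaged per-patient results table
#'
#' Loads the packaged table of per-patient training/testing parameters and
#' prospective performances for the 53-patient multicenter cohort (sampling
#' rate, seizure-focus codes, optimized coupling band, phase interval
#' center, threshold, training and testing sensitivity/FPR, per-patient
#' significance against the random predictor, and which spectral band-power
#' baselines reached significance).
#'
#' @return data frame, one row per patient.
#' @export
load_patient_table <- function() {
  path <- system.file("extdata", "patient_results.csv",
                      package = "cfcpredict", mustWork = TRUE)
  utils::read.csv(path, colClasses = c(
    id = "integer", fs_hz = "integer", focus = "character",
    n_channels = "integer", train_dur_h = "numeric",
    train_n_seizures = "integer", sop_min = "integer",
    band_code = "character", preictal_phase_rad = "numeric",
    threshold_pct = "numeric", train_ss_pct = "numeric",
    train_fpr_h = "numeric", test_dur_h = "numeric",
    test_n_seizures = "integer", test_ss_pct = "numeric",
    test_fpr_h = "numeric", significant = "logical",
    power_sig = "character"))
}

.focus_lobes <- function(focus) {
  unique(substr(strsplit(focus, ",", fixed = TRUE)[[1]], 1, 1))
}

#' Group-level aggregates of a per-patient results table
#'
#' Summarizes prospective testing performance over the patients whose
#' sensitivity beat their random predictor: mean and range of testing
#' sensitivity and FPR, the group-level binomial probability, the preferred
#' preictal duration and coupling band, per-lobe subgroup performance (a
#' patient with both frontal and temporal focus codes counts in both
#' groups), and how many patients each spectral band-power baseline
#' (delta/theta/gamma) identified as significant.
#'
#' @param table a data frame shaped like [load_patient_table()].
#' @param alpha_patient per-patient significance level entering the group
#'   binomial (default 0.05).
#' @return list of aggregates (see Details in the vignette).
#' @export
summarize_results_table <- function(table, alpha_patient = 0.05) {
  if (nrow(table) == 0) stop("empty results table")
  sig <- table[table$significant, , drop = FALSE]
  n_sig <- nrow(sig)

  lobes <- lapply(table$focus, .focus_lobes)
  in_lobe <- function(rows, code) {
    vapply(lobes[rows], function(l) code %in% l, TRUE)
  }
  sig_rows <- which(table$significant)
  lobe_stats <- function(code) {
    idx <- sig_rows[in_lobe(sig_rows, code)]
    list(n = length(idx),
         mean_ss_pct = if (length(idx)) mean(table$test_ss_pct[idx]) else NA,
         mean_fpr_h = if (length(idx)) mean(table$test_fpr_h[idx]) else NA)
  }
  power_counts <- vapply(c("D", "T", "G"), function(b) {
    sum(grepl(b, table$power_sig, fixed = TRUE))
  }, integer(1))

  list(
    n_patients = nrow(table),
    n_significant = n_sig,
    pct_significant = 100 * n_sig / nrow(table),
    group_p = group_significance(n_sig, nrow(table), alpha_patient),
    mean_test_ss_pct = if (n_sig) mean(sig$test_ss_pct) else NA,
    range_test_ss_pct = if (n_sig) range(sig$test_ss_pct) else c(NA, NA),
    mean_test_fpr_h = if (n_sig) mean(sig$test_fpr_h) else NA,
    range_test_fpr_h = if (n_sig) range(sig$test_fpr_h) else c(NA, NA),
    n_sop60 = sum(sig$sop_min == 60),
    n_slow_lg = sum(sig$band_code == "LD"),
    band_counts = table(factor(sig$band_code,
                               levels = c("LD", "LT", "HD", "HT"))),
    temporal = lobe_stats("t"),
    frontal = lobe_stats("f"),
    power_sig_counts = power_counts
  )
}
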