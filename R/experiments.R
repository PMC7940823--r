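# The three end-to-end experiments run on synthetic cohorts: precision /
# convergence of the adaptive estimate, within-visit repeatability of the
# qCSF features against a quantized chart outcome, and MS-vs-control
# discrimination.  Each is a pure function of (configuration, seed):
# reruns are byte-identical, and CSV tables are the contract surface
# (plots are left to the analysis scripts).

cohort_seeded <- function(spec, seed, stream) {
  spec$seed <- substream_seed(seed, 0L, stream = stream)
  spec
}

spec_as_list <- function(spec) unclass(spec)

#' Precision / convergence experiment
#'
#' Simulates one long adaptive session per eye of the precision cohort,
#' records the AULCSF posterior trajectory (estimate and 68.3% credible
#' interval per trial), and compares the estimates after `n_trials` and
#' `n_trials_long` trials with a paired one-sample t-test of the
#' differences ([paired_bias()]).
#'
#' @param spec cohort specification; the default mirrors a 54-subject
#'   cohort with 2 monocular subjects and 1 technical exclusion, i.e. 105
#'   measurements.
#' @param engine a [qcsf_engine()].
#' @param n_trials short-test length (default 25).
#' @param n_trials_long long-test length (default 50); must be >=
#'   `n_trials`.
#' @param seed top-level integer seed.
#' @param out_dir optional output directory; when given, writes
#'   `convergence.csv`, `summary.csv`, `bias.csv`, `config.yaml`,
#'   `run.log`.
#' @return A list: `convergence` (per eye x trial), `summary` (per-trial
#'   mean estimate and mean credible-interval bounds), `bias`
#'   ([paired_bias()] of the 25- vs 50-trial estimates), `cohort`.
#' @export
run_precision_experiment <- function(spec = cohort_spec("MS", 54L,
                                                        n_single_eye = 2L,
                                                        n_excluded = 1L),
                                     engine = qcsf_engine(),
                                     n_trials = 25L, n_trials_long = 50L,
                                     seed = 1L, out_dir = NULL) {
  if (n_trials_long < n_trials) stop("n_trials_long must be >= n_trials")
  cohort <- sample_cohort(cohort_seeded(spec, seed, 2L))
  n <- nrow(cohort)
  batch <- run_sessions_batch(
    cohort[, c("peak_gain", "peak_freq", "bandwidth", "truncation")],
    engine, n_trials = n_trials_long,
    seeds = substream_seed(seed, seq_len(n), stream = 3L),
    record = "trajectory")
  convergence <- data.frame(
    unit = rep(paste0(cohort$subject_id, "_", cohort$eye),
               each = n_trials_long),
    trial_index = rep(seq_len(n_trials_long), n),
    aulcsf_est = as.vector(batch$est),
    ci_lo = as.vector(batch$ci_lo),
    ci_hi = as.vector(batch$ci_hi),
    stringsAsFactors = FALSE)
  est_short <- convergence$aulcsf_est[convergence$trial_index == n_trials]
  est_long <- convergence$aulcsf_est[convergence$trial_index == n_trials_long]
  bias <- paired_bias(est_short, est_long)
  summary <- do.call(rbind, lapply(split(convergence, convergence$trial_index),
    function(d) data.frame(trial_index = d$trial_index[1],
                           mean_est = mean(d$aulcsf_est),
                           mean_ci_lo = mean(d$ci_lo),
                           mean_ci_hi = mean(d$ci_hi),
                           mean_ci_width = mean(d$ci_hi - d$ci_lo))))
  rownames(summary) <- NULL
  summary <- summary[order(summary$trial_index), ]
  out <- list(convergence = convergence, summary = summary, bias = bias,
              cohort = cohort)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_exact(convergence, file.path(out_dir, "convergence.csv"))
    write_csv_exact(summary, file.path(out_dir, "summary.csv"))
    write_csv_exact(as.data.frame(bias), file.path(out_dir, "bias.csv"))
    dump_config(out_dir, list(experiment = "precision",
                              cohort = spec_as_list(spec),
                              n_trials = n_trials,
                              n_trials_long = n_trials_long, seed = seed))
    write_run_log(out_dir, c(
      sprintf("precision experiment: %d measurements, %d/%d trials, seed %d",
              n, n_trials, n_trials_long, seed),
      attr(cohort, "exclusions")))
  }
  out
}

#' Within-visit repeatability experiment
#'
#' Simulates two consecutive adaptive sessions per eye (qCSF features:
#' AULCSF, CSF acuity, CS4) plus two Snellen chart administrations
#' (VA500), computes COR and MAP per feature, and reports whether the
#' quantization reversal holds: VA500 showing the smallest COR (seemingly
#' most repeatable) yet the lowest MAP (least resolving).
#'
#' @param spec cohort specification; default mirrors a 44-subject cohort
#'   with one single-eye subject, i.e. 87 test-retest pairs.
#' @param engine a [qcsf_engine()].
#' @param n_trials adaptive trials per session (default 25).
#' @param chart a [snellen_chart()].
#' @param seed top-level integer seed.
#' @param out_dir optional output directory (`test_retest.csv`,
#'   `report.csv`, `config.yaml`, `run.log`).
#' @return A list: `table` (long test-retest table including the `va500`
#'   feature), `report` ([repeatability_report()] output), `ordering`
#'   (logical flags `va500_cor_smallest`, `va500_map_lowest`), `cohort`.
#' @export
run_repeatability_experiment <- function(spec = cohort_spec("MS", 44L,
                                                            n_single_eye = 1L),
                                         engine = qcsf_engine(),
                                         n_trials = 25L,
                                         chart = snellen_chart(),
                                         seed = 1L, out_dir = NULL) {
  cohort <- sample_cohort(cohort_seeded(spec, seed, 4L))
  table <- simulate_test_retest(cohort, engine, n_trials = n_trials,
                                seed = seed,
                                retest_jitter_sd = spec$retest_jitter_sd)
  va <- t(vapply(seq_len(nrow(cohort)), function(i) {
    obs <- make_observer(as_csf_params(cohort[i, ]), engine$psy)
    c(simulate_va500(obs, chart, seed = substream_seed(seed, i, stream = 5L)),
      simulate_va500(obs, chart, seed = substream_seed(seed, i, stream = 6L)))
  }, numeric(2)))
  table <- rbind(table, data.frame(
    subject_id = cohort$subject_id, eye = cohort$eye, group = cohort$group,
    feature = "va500", test = va[, 1], retest = va[, 2],
    stringsAsFactors = FALSE))
  report <- repeatability_report(table)
  cont <- report$feature != "va500"
  ordering <- list(
    va500_cor_smallest = report$cor[report$feature == "va500"] <
      min(report$cor[cont]),
    va500_map_lowest = report$map[report$feature == "va500"] <
      min(report$map[cont]))
  excl <- attr(cohort, "exclusions")
  cs4_dropped <- report$n_excluded[report$feature == "cs4"]
  if (cs4_dropped > 0) {
    miss <- table$feature == "cs4" & (is.na(table$test) | is.na(table$retest))
    excl <- c(excl, sprintf(
      "%s %s: excluded from CS4 (criterion sensitivity not reached)",
      table$subject_id[miss], table$eye[miss]))
  }
  out <- list(table = table, report = report, ordering = ordering,
              cohort = cohort, exclusions = excl)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_test_retest(table, file.path(out_dir, "test_retest.csv"))
    write_csv_exact(report, file.path(out_dir, "report.csv"))
    dump_config(out_dir, list(experiment = "repeatability",
                              cohort = spec_as_list(spec),
                              n_trials = n_trials, seed = seed))
    write_run_log(out_dir, c(
      sprintf("repeatability experiment: %d pairs, %d trials, seed %d",
              nrow(cohort), n_trials, seed),
      sprintf("quantization reversal: cor %s, map %s",
              ordering$va500_cor_smallest, ordering$va500_map_lowest),
      excl))
  }
  out
}

#' Group-discrimination experiment
#'
#' Calibrates the impaired and control cohort specifications to target
#' group-mean AULCSF levels, measures every eye with the adaptive
#' procedure, averages eye-level AULCSF per subject, and compares the
#' groups with Welch's t-test.  Also emits mean +/- SEM estimated
#' log-sensitivity curves per group over a frequency grid.
#'
#' @param ms_spec,hc_spec cohort specifications (defaults: 13 MS-like vs
#'   61 control-like subjects, two eyes each).
#' @param targets named target mean true AULCSF per group
#'   (default `c(MS = 1.21, HC = 1.42)`); set to `NULL` to skip
#'   calibration.
#' @param engine a [qcsf_engine()].
#' @param n_trials adaptive trials per session (default 25).
#' @param seed top-level integer seed.
#' @param curve_freqs frequencies (cpd) at which the group mean curves
#'   are evaluated.
#' @param out_dir optional output directory (`subjects.csv`,
#'   `welch.csv`, `curves.csv`, `config.yaml`, `run.log`).
#' @return A list: `subjects` (per-subject mean measured AULCSF),
#'   `welch` ([welch_t_test()] result, MS minus HC), `curves` (per group
#'   x frequency: mean and SEM of the posterior-mean log sensitivity),
#'   `specs` (the calibrated specifications).
#' @export
run_discrimination_experiment <- function(ms_spec = cohort_spec("MS", 13L),
                                          hc_spec = cohort_spec("HC", 61L),
                                          targets = c(MS = 1.21, HC = 1.42),
                                          engine = qcsf_engine(),
                                          n_trials = 25L, seed = 1L,
                                          curve_freqs = 10^seq(log10(1), log10(36),
                                                               length.out = 20),
                                          out_dir = NULL) {
  if (!is.null(targets)) {
    ms_spec <- calibrate_group_location(ms_spec, targets[["MS"]])
    hc_spec <- calibrate_group_location(hc_spec, targets[["HC"]])
  }
  # log-sensitivity of every grid point at the curve frequencies (N x F)
  sfmat <- vapply(curve_freqs,
                  function(f) log_sensitivity(as_csf_params(engine$points), f),
                  numeric(nrow(engine$points)))
  measure_group <- function(spec, stream) {
    cohort <- sample_cohort(cohort_seeded(spec, seed, stream))
    n <- nrow(cohort)
    batch <- run_sessions_batch(
      cohort[, c("peak_gain", "peak_freq", "bandwidth", "truncation")],
      engine, n_trials = n_trials,
      seeds = substream_seed(seed, seq_len(n), stream = stream + 10L))
    aul <- batch$final$aulcsf
    curves <- t(crossprod(sfmat, batch$mass))      # sessions x freqs
    subj <- unique(cohort$subject_id)
    subj_aul <- vapply(subj, function(s) mean(aul[cohort$subject_id == s]),
                       numeric(1))
    subj_curves <- t(vapply(subj, function(s) {
      colMeans(curves[cohort$subject_id == s, , drop = FALSE])
    }, numeric(length(curve_freqs))))
    list(cohort = cohort, subj = subj, subj_aul = subj_aul,
         subj_curves = subj_curves)
  }
  ms <- measure_group(ms_spec, 7L)
  hc <- measure_group(hc_spec, 8L)
  subjects <- data.frame(
    subject_id = c(ms$subj, hc$subj),
    group = rep(c("MS", "HC"), c(length(ms$subj), length(hc$subj))),
    mean_aulcsf = c(ms$subj_aul, hc$subj_aul),
    stringsAsFactors = FALSE)
  welch <- welch_t_test(ms$subj_aul, hc$subj_aul)
  curve_df <- function(g, m) data.frame(
    group = g, freq_cpd = curve_freqs,
    mean_log_sensitivity = colMeans(m),
    sem = apply(m, 2, stats::sd) / sqrt(nrow(m)))
  curves <- rbind(curve_df("MS", ms$subj_curves), curve_df("HC", hc$subj_curves))
  out <- list(subjects = subjects, welch = welch, curves = curves,
              specs = list(MS = ms_spec, HC = hc_spec))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_exact(subjects, file.path(out_dir, "subjects.csv"))
    write_csv_exact(data.frame(t = welch$t, df = welch$df, p = welch$p,
                               ci_lo = welch$ci[1], ci_hi = welch$ci[2],
                               mean_diff = welch$mean_diff),
                    file.path(out_dir, "welch.csv"))
    write_csv_exact(curves, file.path(out_dir, "curves.csv"))
    dump_config(out_dir, list(experiment = "discrimination",
                              cohort_ms = spec_as_list(ms_spec),
                              cohort_hc = spec_as_list(hc_spec),
                              n_trials = n_trials, seed = seed))
    write_run_log(out_dir, sprintf(
      "discrimination experiment: %d vs %d subjects, Welch t(%0.2f) = %0.2f, p = %.3g",
      length(ms$subj), length(hc$subj), welch$df, welch$t, welch$p))
  }
  out
}
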