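# Synthetic observers, cohorts with test-retest structure, and the
# quantized Snellen chart outcome.

# deterministic 32-bit substream seed for unit `index` within stream
# `stream` of a top-level seed; stable under cohort-size changes
substream_seed <- function(seed, index, stream = 0L) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 999983 +
                as.double(index) * 104729) %% 2147483629) + 1L
}

#' Simulated observer
#'
#' An in-silico stand-in for a tested eye: true CSF parameters plus the
#' psychometric response model.  Each presented letter is answered
#' correctly with probability [response_probability()] at the observer's
#' true parameters, independently across letters.
#'
#' @param params a [csf_params()] object (one observer).
#' @param psy a [psychometric_config()].
#' @param seed optional integer seed making the observer's response
#'   stream deterministic when no session seed is given.
#' @return An object of class `observer`.
#' @export
make_observer <- function(params, psy = psychometric_config(), seed = NULL) {
  params <- as_csf_params(params)
  if (length(params$peak_gain) != 1L) stop("one observer at a time")
  structure(list(params = params, psy = psy, seed = seed),
            class = "observer")
}

#' Draw letter responses from an observer
#'
#' Uses the current RNG state (seed it, or rely on [run_session()] /
#' [simulate_va500()] doing so).
#'
#' @param observer a [make_observer()] object.
#' @param stim a [stimulus()].
#' @param n_letters number of independent letters.
#' @return Logical vector of per-letter correctness.
#' @export
observer_respond <- function(observer, stim, n_letters = observer$psy$letters_per_trial) {
  p <- response_probability(observer$params, stim, observer$psy)
  stats::runif(n_letters) < p
}

#' Cohort generating specification
#'
#' Describes a group of subjects whose true CSF parameters are drawn from
#' independent Gaussians in transformed space: peak gain and truncation on
#' the identity (log10-sensitivity) scale, peak frequency and bandwidth on
#' the log10 scale.  Within-subject eyes share a subject-level component;
#' `eye_correlation` is the between-eye correlation of each parameter.
#'
#' Group defaults place the mean AULCSF near the impaired (MS-like, peak
#' gain location 1.33) or healthy (HC-like, 1.56) level; use
#' [calibrate_group_location()] to hit a group-mean AULCSF target exactly.
#'
#' @param group `"MS"` or `"HC"` (label only; sets the default gain
#'   location).
#' @param n_subjects number of subjects, at least 2.
#' @param eyes_per_subject eyes contributed per subject (default 2).
#' @param n_single_eye number of subjects contributing one eye only
#'   (e.g. no remaining vision in the fellow eye).
#' @param n_excluded measurements dropped after sampling (technical
#'   failures); removed from the end of the table and logged.
#' @param gain_mean,gain_sd peak gain location/scale, log10 units.
#' @param log_freq_mean,log_freq_sd log10 peak frequency location/scale.
#' @param log_bw_mean,log_bw_sd log10 bandwidth location/scale.
#' @param trunc_mean,trunc_sd truncation location/scale (draws clipped at
#'   0.01).
#' @param eye_correlation between-eye correlation of each parameter, in
#'   [0, 1] (default 0.7).
#' @param retest_jitter_sd SD of a per-assessment perturbation of peak
#'   gain modelling true-state fluctuation between immediate test and
#'   retest; default 0 (within-visit design: response stochasticity is the
#'   only noise source).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group = c("MS", "HC"), n_subjects,
                        eyes_per_subject = 2L, n_single_eye = 0L,
                        n_excluded = 0L,
                        gain_mean = if (group == "MS") 1.33 else 1.56,
                        gain_sd = 0.09,
                        log_freq_mean = log10(2.2), log_freq_sd = 0.07,
                        log_bw_mean = log10(3.2), log_bw_sd = 0.055,
                        trunc_mean = 0.4, trunc_sd = 0.07,
                        eye_correlation = 0.7, retest_jitter_sd = 0,
                        seed = 1L) {
  group <- match.arg(group)
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (any(c(gain_sd, log_freq_sd, log_bw_sd, trunc_sd, retest_jitter_sd) < 0))
    stop("scales must be >= 0")
  if (eye_correlation < 0 || eye_correlation > 1)
    stop("eye_correlation must lie in [0, 1]")
  if (n_single_eye > n_subjects) stop("n_single_eye exceeds n_subjects")
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 eyes_per_subject = as.integer(eyes_per_subject),
                 n_single_eye = as.integer(n_single_eye),
                 n_excluded = as.integer(n_excluded),
                 gain_mean = gain_mean, gain_sd = gain_sd,
                 log_freq_mean = log_freq_mean, log_freq_sd = log_freq_sd,
                 log_bw_mean = log_bw_mean, log_bw_sd = log_bw_sd,
                 trunc_mean = trunc_mean, trunc_sd = trunc_sd,
                 eye_correlation = eye_correlation,
                 retest_jitter_sd = retest_jitter_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# draw one parameter for n_subjects x n_eyes with between-eye correlation
# rho: subject component variance rho*sd^2, eye component (1-rho)*sd^2
draw_correlated <- function(n_subjects, n_eyes, mean, sd, rho) {
  subj <- stats::rnorm(n_subjects, 0, sd * sqrt(rho))
  eye <- matrix(stats::rnorm(n_subjects * n_eyes, 0, sd * sqrt(1 - rho)),
                n_subjects, n_eyes)
  mean + subj + eye
}

#' Sample a synthetic cohort
#'
#' Draws true CSF parameters for every eye of every subject per the spec;
#' single-eye subjects contribute their first eye only, and
#' `n_excluded` trailing measurements are dropped (the exclusions are
#' recorded in the `"exclusions"` attribute).
#'
#' @param spec a [cohort_spec()].
#' @return A data.frame with columns `subject_id`, `eye` (`"OD"`/`"OS"`),
#'   `group`, `peak_gain`, `peak_freq`, `bandwidth`, `truncation`; one row
#'   per analysis unit (eye).  Reproducible given `spec$seed`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ns <- spec$n_subjects; ne <- spec$eyes_per_subject
  rho <- spec$eye_correlation
  gain <- draw_correlated(ns, ne, spec$gain_mean, spec$gain_sd, rho)
  lfreq <- draw_correlated(ns, ne, spec$log_freq_mean, spec$log_freq_sd, rho)
  lbw <- draw_correlated(ns, ne, spec$log_bw_mean, spec$log_bw_sd, rho)
  trunc <- pmax(draw_correlated(ns, ne, spec$trunc_mean, spec$trunc_sd, rho),
                0.01)
  eye_names <- c("OD", "OS", paste0("E", seq_len(max(0, ne - 2)) + 2))[seq_len(ne)]
  tab <- data.frame(
    subject_id = rep(sprintf("%s%03d", spec$group, seq_len(ns)), each = ne),
    eye = rep(eye_names, ns),
    group = spec$group,
    peak_gain = as.vector(t(gain)),
    peak_freq = 10^as.vector(t(lfreq)),
    bandwidth = 10^as.vector(t(lbw)),
    truncation = as.vector(t(trunc)),
    stringsAsFactors = FALSE
  )
  exclusions <- character(0)
  if (spec$n_single_eye > 0) {
    mono <- sprintf("%s%03d", spec$group, seq_len(spec$n_single_eye))
    drop <- tab$subject_id %in% mono & tab$eye != eye_names[1]
    exclusions <- c(exclusions,
                    sprintf("%s %s: fellow eye not measurable (monocular subject)",
                            tab$subject_id[drop], tab$eye[drop]))
    tab <- tab[!drop, , drop = FALSE]
  }
  if (spec$n_excluded > 0) {
    drop <- seq.int(nrow(tab) - spec$n_excluded + 1, nrow(tab))
    exclusions <- c(exclusions,
                    sprintf("%s %s: measurement excluded (technical failure)",
                            tab$subject_id[drop], tab$eye[drop]))
    tab <- tab[-drop, , drop = FALSE]
  }
  rownames(tab) <- NULL
  attr(tab, "exclusions") <- exclusions
  tab
}

#' Calibrate a cohort's peak-gain location to a mean AULCSF target
#'
#' Shifts the `gain_mean` of the spec by bisection until the Monte-Carlo
#' mean true AULCSF of the generating distribution (fixed internal seed,
#' `n_draws` parameter draws) is within `tolerance` of the target.  The
#' mean AULCSF is nondecreasing in the gain location, so bisection is
#' exact on the Monte-Carlo objective.
#'
#' @param spec a [cohort_spec()].
#' @param target_mean_aulcsf target group-mean AULCSF.
#' @param tolerance absolute tolerance (default 0.005).
#' @param max_iter bisection iterations allowed (default 60).
#' @param n_draws Monte-Carlo draws (default 4000).
#' @return The spec with `gain_mean` adjusted.
#' @export
calibrate_group_location <- function(spec, target_mean_aulcsf,
                                     tolerance = 0.005, max_iter = 60L,
                                     n_draws = 4000L) {
  stopifnot(inherits(spec, "cohort_spec"), n_draws >= 2000)
  # fixed internal draws in standardized form; shift enters analytically
  set.seed(20240229L)
  z_gain <- stats::rnorm(n_draws)
  lfreq <- stats::rnorm(n_draws, spec$log_freq_mean, spec$log_freq_sd)
  lbw <- stats::rnorm(n_draws, spec$log_bw_mean, spec$log_bw_sd)
  trunc <- pmax(stats::rnorm(n_draws, spec$trunc_mean, spec$trunc_sd), 0.01)
  mean_aulcsf <- function(loc) {
    mean(aulcsf(csf_params(loc + spec$gain_sd * z_gain, 10^lfreq,
                           10^lbw, trunc)))
  }
  lo <- spec$gain_mean - 3; hi <- spec$gain_mean + 3
  if (mean_aulcsf(lo) > target_mean_aulcsf + tolerance ||
      mean_aulcsf(hi) < target_mean_aulcsf - tolerance)
    stop("calibration target outside achievable range [",
         round(mean_aulcsf(lo), 3), ", ", round(mean_aulcsf(hi), 3), "]")
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- mean_aulcsf(mid)
    if (abs(val - target_mean_aulcsf) <= tolerance) {
      spec$gain_mean <- mid
      attr(spec, "calibration") <- list(target = target_mean_aulcsf,
                                        achieved = val, iterations = it)
      return(spec)
    }
    if (val < target_mean_aulcsf) lo <- mid else hi <- mid
  }
  stop("calibration did not converge in ", max_iter,
       " iterations (last mean ", round(val, 4), ", target ",
       target_mean_aulcsf, ")")
}

#' Simulate within-visit test--retest measurements
#'
#' Runs two independent adaptive sessions per eye (fresh response
#' randomness, identical true parameters unless `retest_jitter_sd` in the
#' attached spec is positive) and extracts the qCSF features.  Missing
#' features (e.g. CS4 for an eye that cannot reach 25% contrast) are
#' propagated as `NA`, never imputed.
#'
#' @param cohort a [sample_cohort()] table.
#' @param engine a [qcsf_engine()].
#' @param n_trials adaptive trials per session (default 25).
#' @param seed top-level integer seed; per-eye substreams are derived
#'   deterministically so adding eyes does not reshuffle existing ones.
#' @param psy the observers' true psychometric model (defaults to the
#'   engine's).
#' @param retest_jitter_sd SD of a peak-gain perturbation applied
#'   independently to each assessment (default 0).
#' @return A data.frame in long format: `subject_id`, `eye`, `group`,
#'   `feature` (aulcsf, csf_acuity, cs4), `test`, `retest`.
#' @export
simulate_test_retest <- function(cohort, engine, n_trials = 25L, seed = 1L,
                                 psy = engine$psy, retest_jitter_sd = 0) {
  n <- nrow(cohort)
  feats <- c("aulcsf", "csf_acuity", "cs4")
  assess <- function(rep_idx) {
    seeds <- substream_seed(seed, 2L * seq_len(n) - 2L + rep_idx, stream = 1L)
    params <- cohort[, c("peak_gain", "peak_freq", "bandwidth", "truncation")]
    if (retest_jitter_sd > 0) {
      for (i in seq_len(n)) {
        set.seed(substream_seed(seeds[i], rep_idx, stream = 9L))
        params$peak_gain[i] <- params$peak_gain[i] +
          stats::rnorm(1, 0, retest_jitter_sd)
      }
    }
    fin <- run_sessions_batch(params, engine, n_trials = n_trials,
                              seeds = seeds, psy = psy)$final
    cbind(aulcsf = fin$aulcsf, csf_acuity = fin$csf_acuity, cs4 = fin$cs4)
  }
  test <- assess(1L)
  retest <- assess(2L)
  data.frame(
    subject_id = rep(cohort$subject_id, times = length(feats)),
    eye = rep(cohort$eye, times = length(feats)),
    group = rep(cohort$group, times = length(feats)),
    feature = rep(feats, each = n),
    test = as.vector(test),
    retest = as.vector(retest),
    stringsAsFactors = FALSE
  )
}

#' Nine-line Snellen chart specification
#'
#' Lines ordered from the largest letters (LogMAR 1) to the smallest
#' (LogMAR -0.1), with the standard nine LogMAR levels, 1--10 letters per
#' line, and each line's equivalent spatial frequency from the optotype
#' stroke-frequency convention `30 / 10^LogMAR` cpd.
#'
#' @param logmar the nine LogMAR values, strictly decreasing from the
#'   largest to the smallest letters.
#' @param letters letters per line (1--10).
#' @return A data.frame of class `chart_spec` with columns `logmar`,
#'   `letters`, `freq_cpd`.
#' @export
snellen_chart <- function(logmar = c(1, 0.85, 0.7, 0.6, 0.5, 0.3, 0.2, 0, -0.1),
                          letters = c(1, 2, 3, 4, 5, 6, 8, 9, 10)) {
  if (length(logmar) != 9 || length(letters) != 9)
    stop("a chart has exactly nine lines")
  if (any(diff(logmar) >= 0))
    stop("LogMAR must strictly decrease from the largest letters down")
  if (any(letters < 1) || any(letters > 10))
    stop("letters per line must lie in 1..10")
  structure(data.frame(logmar = logmar, letters = as.integer(letters),
                       freq_cpd = 30 / 10^logmar),
            class = c("chart_spec", "data.frame"))
}

#' Simulate a Snellen chart reading (VA500)
#'
#' Each letter of each line is read correctly, independently, with
#' probability [response_probability()] at the line's equivalent spatial
#' frequency and full (100%) contrast.  The outcome is the LogMAR of the
#' smallest line read with fewer than two mistakes; a line must also have
#' at least one correct letter so a wholly failed one-letter line cannot
#' qualify.  If no line qualifies the worst chart value (LogMAR 1) is
#' returned.  The result is always one of the chart's nine values.
#'
#' Chart reading is self-paced with unlimited viewing time, so per-letter
#' attention lapses are rarer than during brief adaptive presentations;
#' `lapse` overrides the observer's lapse rate for the chart only
#' (default 0.01, at which simulated chart repeatability sits in the
#' range reported for high-contrast acuity charts).
#'
#' @param observer a [make_observer()] object.
#' @param chart a [snellen_chart()].
#' @param seed optional integer seed.
#' @param lapse chart-specific lapse rate.
#' @return A LogMAR value from the chart's value set.
#' @export
simulate_va500 <- function(observer, chart = snellen_chart(), seed = NULL,
                           lapse = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  psy <- observer$psy
  psy$lapse <- lapse
  best <- NA_real_
  for (i in seq_len(nrow(chart))) {
    p <- response_probability(observer$params,
                              list(freq = chart$freq_cpd[i], contrast = 1),
                              psy)
    correct <- stats::runif(chart$letters[i]) < p
    mistakes <- sum(!correct)
    if (mistakes <= 1 && sum(correct) >= 1) best <- chart$logmar[i]
  }
  if (is.na(best)) best <- max(chart$logmar)
  best
}
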