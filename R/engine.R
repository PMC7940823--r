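# Grid-based Bayesian adaptive CSF estimation: posterior updates,
# information-gain stimulus selection, and full simulated test sessions.

#' Uniform posterior over a parameter grid
#'
#' @param grid a [build_grid()] object, or a data.frame of grid points
#'   with the four CSF parameter columns.
#' @return An object of class `csf_posterior` with `points` (data.frame)
#'   and `mass` (probability vector summing to 1).
#' @export
uniform_posterior <- function(grid) {
  points <- if (inherits(grid, "param_grid")) grid$points else as.data.frame(grid)
  n <- nrow(points)
  if (n < 1) stop("empty grid")
  structure(list(points = points, mass = rep(1 / n, n)),
            class = "csf_posterior")
}

# binary entropy in bits, 0 log 0 = 0; keeps matrix dimensions
binary_entropy <- function(p) {
  h <- p
  h[] <- 0
  ok <- p > 0 & p < 1
  q <- p[ok]
  h[ok] <- -(q * log2(q) + (1 - q) * log2(1 - q))
  h
}

#' Bayesian posterior update from letter responses
#'
#' Applies Bayes' rule once per letter, sequentially: grid point `i` with
#' per-letter probability `p_i` of a correct response gets its mass
#' multiplied by `p_i` (letter correct) or `1 - p_i` (incorrect), then the
#' posterior is renormalized.  Deterministic; with a positive guess rate
#' and lapse rate the likelihood is bounded away from 0 and 1 so the
#' posterior cannot collapse.
#'
#' @param post a `csf_posterior`.
#' @param stim a [stimulus()] (one size/contrast; all letters of a trial
#'   share it).
#' @param outcomes logical vector of per-letter correctness.
#' @param psy a [psychometric_config()].
#' @return The updated `csf_posterior`.
#' @export
update_posterior <- function(post, stim, outcomes, psy = psychometric_config()) {
  p <- response_probability(as_csf_params(post$points), stim, psy)
  mass <- post$mass
  for (ok in outcomes) {
    mass <- mass * (if (ok) p else 1 - p)
    tot <- sum(mass)
    if (tot <= 0) stop("posterior mass vanished during update")
    mass <- mass / tot
  }
  post$mass <- mass
  post
}

#' Expected one-letter information gain of a stimulus
#'
#' Mutual information (bits) between the next letter outcome and the CSF
#' parameters: `I = H(sum_i m_i p_i) - sum_i m_i H(p_i)` with `H` the
#' binary entropy.  Nonnegative; zero when every supported grid point
#' predicts the same response probability.
#'
#' @inheritParams update_posterior
#' @return Expected information gain in bits.
#' @export
expected_information_gain <- function(post, stim, psy = psychometric_config()) {
  p <- response_probability(as_csf_params(post$points), stim, psy)
  pbar <- sum(post$mass * p)
  binary_entropy(pbar) - sum(post$mass * binary_entropy(p))
}

#' Most informative stimulus from a candidate set
#'
#' Argmax of [expected_information_gain()] over the candidate stimuli;
#' ties are broken by the lowest grid index for determinism.
#'
#' @param post a `csf_posterior`.
#' @param stimuli data.frame of candidates (`freq`, `contrast`), e.g. from
#'   [stimulus_grid()].
#' @param psy a [psychometric_config()].
#' @return The selected [stimulus()], with attributes `index` (row in
#'   `stimuli`) and `gain` (bits).
#' @export
select_stimulus <- function(post, stimuli, psy = psychometric_config()) {
  if (NROW(stimuli) < 1) stop("empty stimulus grid")
  pm <- response_matrix(post$points, stimuli, psy)
  pbar <- drop(crossprod(pm, post$mass))
  gains <- binary_entropy(pbar) - drop(crossprod(binary_entropy(pm), post$mass))
  i <- which.max(gains)   # first maximum: lowest-index tie-break
  out <- stimulus(stimuli$freq[i], stimuli$contrast[i])
  attr(out, "index") <- i
  attr(out, "gain") <- gains[i]
  out
}

# N x S matrix of per-letter response probabilities, grid points x stimuli
response_matrix <- function(points, stimuli, psy) {
  params <- as_csf_params(points)
  n <- length(params$peak_gain)
  s <- NROW(stimuli)
  m <- matrix(0, n, s)
  for (j in seq_len(s)) {
    m[, j] <- response_probability(
      params, list(freq = stimuli$freq[j], contrast = stimuli$contrast[j]), psy)
  }
  m
}

# smallest value whose weighted CDF reaches q, given values sorted
# ascending and their cumulative weights
weighted_quantile_sorted <- function(values_sorted, cumw, q) {
  values_sorted[pmin(length(cumw), findInterval(q, cumw, left.open = TRUE) + 1L)]
}

#' Posterior estimate and credible interval of a CSF feature
#'
#' The scalar estimate is the posterior mean of the feature over the grid
#' (marginalizing over the full joint posterior); the interval is the
#' central credible interval of the feature's posterior distribution via
#' mass-weighted quantiles.
#'
#' @param post a `csf_posterior`.
#' @param feature either a function mapping a [csf_params()] vector to
#'   feature values, or a precomputed numeric vector with one value per
#'   grid point.
#' @param credible_level central interval coverage, in (0, 1); default
#'   0.683.
#' @return A list `estimate`, `lower`, `upper`.
#' @export
posterior_feature_estimate <- function(post, feature, credible_level = 0.683) {
  if (!(credible_level > 0 && credible_level < 1))
    stop("credible_level must lie in (0, 1)")
  v <- if (is.function(feature)) feature(as_csf_params(post$points)) else feature
  if (length(v) != length(post$mass)) stop("feature length mismatch")
  est <- sum(post$mass * v)
  ord <- order(v)
  cw <- cumsum(post$mass[ord])
  a <- (1 - credible_level) / 2
  list(estimate = est,
       lower = weighted_quantile_sorted(v[ord], cw, a),
       upper = weighted_quantile_sorted(v[ord], cw, 1 - a))
}

#' Precomputed adaptive testing engine
#'
#' Bundles the parameter grid, candidate stimuli and psychometric model,
#' and caches the response-probability and entropy matrices plus the
#' per-grid-point feature values, so that simulated sessions reduce to a
#' few matrix-vector products per trial.  The stimulus-selection lookahead
#' is one letter (not the full multi-letter trial).
#'
#' Default sizes (12 x 10 x 6 x 5 parameter grid, 15 x 13 stimulus grid)
#' are a compact profile adequate for the features studied here; pass a
#' finer [build_grid()] / [stimulus_grid()] for higher-resolution
#' posteriors at proportionally higher memory and time cost.
#'
#' @param grid a [build_grid()] object.
#' @param stimuli a [stimulus_grid()] data.frame.
#' @param psy a [psychometric_config()] assumed by the engine.
#' @param band a [freq_band()] for the AULCSF feature.
#' @param cs4_threshold log10 sensitivity criterion for CS4.
#' @param credible_level central credible interval coverage.
#' @return An object of class `qcsf_engine`.
#' @export
qcsf_engine <- function(grid = build_grid(12L, 10L, 6L, 5L),
                        stimuli = stimulus_grid(15L, 13L),
                        psy = psychometric_config(),
                        band = freq_band(),
                        cs4_threshold = log10(4),
                        credible_level = 0.683) {
  points <- grid$points
  params <- as_csf_params(points)
  p <- response_matrix(points, stimuli, psy)
  aulcsf_g <- aulcsf(params, band)
  ord <- order(aulcsf_g)
  structure(list(
    grid = grid, points = points, stimuli = stimuli, psy = psy,
    band = band, cs4_threshold = cs4_threshold,
    credible_level = credible_level,
    tP = t(p), P = p, tHP = t(binary_entropy(p)),
    aulcsf_g = aulcsf_g, aulcsf_ord = ord,
    aulcsf_sorted = aulcsf_g[ord],
    acuity_g = cutoff_frequency(params, 0),
    cs4_g = cutoff_frequency(params, cs4_threshold)
  ), class = "qcsf_engine")
}

#' @export
print.qcsf_engine <- function(x, ...) {
  cat("qCSF engine:", nrow(x$points), "grid points,",
      nrow(x$stimuli), "candidate stimuli,",
      x$psy$letters_per_trial, "letters/trial\n")
  invisible(x)
}

# posterior-mean of a per-grid-point feature that can be undefined at some
# grid points; NA when the posterior probability of "defined" is < 0.5
masked_posterior_mean <- function(values, mass) {
  def <- !is.na(values)
  pdef <- sum(mass[def])
  if (pdef < 0.5) return(NA_real_)
  sum(mass[def] * values[def]) / pdef
}

#' Simulate one adaptive qCSF test session
#'
#' Runs the adaptive loop: select the most informative stimulus, present
#' `letters_per_trial` letters to the simulated observer (independent
#' Bernoulli outcomes at the observer's true response probability), update
#' the posterior per letter, and record the running AULCSF posterior mean
#' with its credible interval.  Fully reproducible given the seed.
#'
#' @param observer a [make_observer()] object.
#' @param engine a [qcsf_engine()].
#' @param n_trials number of adaptive trials (default 25).
#' @param seed integer seed for the observer's responses; falls back to
#'   the observer's own seed.
#' @return An object of class `qcsf_session`: `letters` (one row per
#'   letter: trial_index, freq_cpd, contrast, letter_index, correct),
#'   `estimates` (per trial: trial_index, aulcsf_est, ci_lo, ci_hi),
#'   `final` (AULCSF with interval, csf_acuity, cs4 -- `NA` when the
#'   posterior puts most mass on the criterion being unattainable), and
#'   the final posterior `mass`.
#' @export
run_session <- function(observer, engine, n_trials = 25L, seed = NULL) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (is.null(seed)) seed <- observer$seed
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(engine$points)
  mass <- rep(1 / n, n)
  nl <- engine$psy$letters_per_trial
  a <- (1 - engine$credible_level) / 2
  sel <- integer(n_trials)
  est <- lo <- hi <- numeric(n_trials)
  correct <- matrix(NA, n_trials, nl)
  for (t in seq_len(n_trials)) {
    pbar <- drop(engine$tP %*% mass)
    gains <- binary_entropy(pbar) - drop(engine$tHP %*% mass)
    j <- which.max(gains)
    sel[t] <- j
    stim <- list(freq = engine$stimuli$freq[j],
                 contrast = engine$stimuli$contrast[j])
    p_true <- response_probability(observer$params, stim, observer$psy)
    outc <- stats::runif(nl) < p_true
    correct[t, ] <- outc
    pcol <- engine$P[, j]
    for (l in seq_len(nl)) {
      mass <- mass * (if (outc[l]) pcol else 1 - pcol)
      mass <- mass / sum(mass)
    }
    est[t] <- sum(mass * engine$aulcsf_g)
    cw <- cumsum(mass[engine$aulcsf_ord])
    lo[t] <- weighted_quantile_sorted(engine$aulcsf_sorted, cw, a)
    hi[t] <- weighted_quantile_sorted(engine$aulcsf_sorted, cw, 1 - a)
  }
  letters <- data.frame(
    trial_index = rep(seq_len(n_trials), each = nl),
    freq_cpd = rep(engine$stimuli$freq[sel], each = nl),
    contrast = rep(engine$stimuli$contrast[sel], each = nl),
    letter_index = rep(seq_len(nl), n_trials),
    correct = as.vector(t(correct))
  )
  structure(list(
    letters = letters,
    estimates = data.frame(trial_index = seq_len(n_trials),
                           aulcsf_est = est, ci_lo = lo, ci_hi = hi),
    final = list(aulcsf = est[n_trials], aulcsf_lo = lo[n_trials],
                 aulcsf_hi = hi[n_trials],
                 csf_acuity = masked_posterior_mean(engine$acuity_g, mass),
                 cs4 = masked_posterior_mean(engine$cs4_g, mass)),
    mass = mass
  ), class = "qcsf_session")
}

#' Simulate many adaptive sessions in lockstep
#'
#' Computationally equivalent to calling [run_session()] once per
#' observer with the matching seed (each observer's response stream is
#' pre-drawn from its own seed, so results do not depend on the batch
#' composition), but the per-trial posterior algebra for all sessions is
#' carried as matrix products, which is what makes the cohort-level
#' Monte-Carlo experiments affordable.  The per-trial mass trajectory
#' agrees with [run_session()] to floating-point rounding.
#'
#' @param cohort_params true CSF parameters, one observer per row: a
#'   data.frame with the four parameter columns or a [csf_params()]
#'   vector.
#' @param engine a [qcsf_engine()].
#' @param n_trials adaptive trials per session.
#' @param seeds integer vector, one seed per observer.
#' @param psy the observers' true psychometric model (defaults to the
#'   engine's assumed one).
#' @param record `"final"` (default) or `"trajectory"` (additionally
#'   keeps the per-trial AULCSF estimate and credible interval of every
#'   session).
#' @return A list: `final` (data.frame with one row per session:
#'   `aulcsf`, `aulcsf_lo`, `aulcsf_hi`, `csf_acuity`, `cs4`), `mass`
#'   (grid-points x sessions matrix of final posterior mass), and -- when
#'   recording trajectories -- `est`, `ci_lo`, `ci_hi` (trials x sessions
#'   matrices).
#' @export
run_sessions_batch <- function(cohort_params, engine, n_trials = 25L, seeds,
                               psy = engine$psy,
                               record = c("final", "trajectory")) {
  record <- match.arg(record)
  params <- as_csf_params(cohort_params)
  k_n <- length(params$peak_gain)
  if (length(seeds) != k_n) stop("need one seed per observer")
  if (n_trials < 1) stop("n_trials must be >= 1")
  nl <- engine$psy$letters_per_trial
  n <- nrow(engine$points)
  u <- matrix(0, n_trials * nl, k_n)
  for (k in seq_len(k_n)) {
    set.seed(seeds[k])
    u[, k] <- stats::runif(n_trials * nl)
  }
  true_p <- response_matrix(
    data.frame(peak_gain = params$peak_gain, peak_freq = params$peak_freq,
               bandwidth = params$bandwidth, truncation = params$truncation),
    engine$stimuli, psy)                             # sessions x stimuli
  mass <- matrix(1 / n, n, k_n)
  a <- (1 - engine$credible_level) / 2
  traj <- record == "trajectory"
  if (traj) est <- lo <- hi <- matrix(0, n_trials, k_n)
  for (t in seq_len(n_trials)) {
    pbar <- engine$tP %*% mass                       # stimuli x sessions
    gains <- binary_entropy(pbar) - engine$tHP %*% mass
    j <- max.col(t(gains), ties.method = "first")
    p_sel <- engine$P[, j, drop = FALSE]
    ptrue <- true_p[cbind(seq_len(k_n), j)]
    for (l in seq_len(nl)) {
      corr <- u[(t - 1L) * nl + l, ] < ptrue
      lik <- p_sel
      if (any(!corr)) lik[, !corr] <- 1 - lik[, !corr]
      mass <- mass * lik
      mass <- mass * rep(1 / colSums(mass), each = n)
    }
    if (traj) {
      est[t, ] <- drop(crossprod(mass, engine$aulcsf_g))
      for (k in seq_len(k_n)) {
        cw <- cumsum(mass[engine$aulcsf_ord, k])
        lo[t, k] <- weighted_quantile_sorted(engine$aulcsf_sorted, cw, a)
        hi[t, k] <- weighted_quantile_sorted(engine$aulcsf_sorted, cw, 1 - a)
      }
    }
  }
  fin_est <- drop(crossprod(mass, engine$aulcsf_g))
  fin_lo <- fin_hi <- acuity <- cs4 <- numeric(k_n)
  for (k in seq_len(k_n)) {
    cw <- cumsum(mass[engine$aulcsf_ord, k])
    fin_lo[k] <- weighted_quantile_sorted(engine$aulcsf_sorted, cw, a)
    fin_hi[k] <- weighted_quantile_sorted(engine$aulcsf_sorted, cw, 1 - a)
    acuity[k] <- masked_posterior_mean(engine$acuity_g, mass[, k])
    cs4[k] <- masked_posterior_mean(engine$cs4_g, mass[, k])
  }
  out <- list(final = data.frame(aulcsf = fin_est, aulcsf_lo = fin_lo,
                                 aulcsf_hi = fin_hi, csf_acuity = acuity,
                                 cs4 = cs4),
              mass = mass)
  if (traj) { out$est <- est; out$ci_lo <- lo; out$ci_hi <- hi }
  out
}
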