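# Bayesian adaptive engine: posterior updates, information gain,
# stimulus selection, feature estimates, full sessions.

# two-point posterior whose response probabilities are analytically known:
# guess 0, lapse 0, slope 1 makes p = 1 - exp(-ln2 * c/tau) invertible
two_point_posterior <- function(p_targets, contrast = 0.1, freq = 3) {
  psy <- psychometric_config(guess = 0, lapse = 0, slope = 1,
                             alternatives = 1L)
  # solve c/tau for each target probability, then the gain that gives tau
  x <- -log(1 - p_targets) / log(2)
  gains <- log10(x / contrast)
  post <- uniform_posterior(data.frame(peak_gain = gains, peak_freq = freq,
                                       bandwidth = 4, truncation = 0))
  list(post = post, psy = psy,
       stim = stimulus(freq = freq, contrast = contrast))
}

test_that("response_probability follows the anchored Weibull form", {
  psy <- psychometric_config(guess = 0.1, lapse = 0.04, slope = 2)
  p <- csf_params(1, 3, 4, 0)          # tau = 0.1 at the peak
  # at threshold contrast: halfway between floor and ceiling
  expect_equal(response_probability(p, stimulus(3, 0.1), psy),
               0.1 + 0.86 * 0.5)
  # c/tau = 4, slope 2: hand evaluation of the formula
  expect_equal(response_probability(p, stimulus(3, 0.4), psy),
               0.1 + 0.86 * (1 - exp(-16 * log(2))), tolerance = 1e-12)
  expect_equal(0.1 + 0.86 * (1 - exp(-16 * log(2))), 0.96, tolerance = 1e-3)
  # vanishing contrast floors at the guess rate
  expect_equal(response_probability(p, list(freq = 3, contrast = 1e-9), psy),
               0.1, tolerance = 1e-6)
})

test_that("build_grid is deterministic, log-spaced and validated", {
  g <- build_grid(2L, 2L, 2L, 2L)
  expect_equal(nrow(g$points), 16)
  expect_equal(prod(vapply(build_grid()$axes, length, 1L)), 90000)
  expect_equal(nrow(build_grid()$points), 90000)
  # log spacing: equal ratios along the frequency axis
  ax <- build_grid(3L, 5L, 3L, 3L)$axes$peak_freq
  expect_equal(diff(log10(ax)), rep(diff(log10(ax))[1], 4))
  expect_error(build_grid(1L, 5L, 5L, 5L), "at least 2")
  expect_error(build_grid(freq_range = c(5, 5)), "range")
  expect_error(build_grid(freq_range = c(7, 2)), "range")
})

test_that("update_posterior reproduces hand Bayes computations", {
  tp <- two_point_posterior(c(0.9, 0.5))
  p <- response_probability(as_csf_params(tp$post$points), tp$stim, tp$psy)
  expect_equal(p, c(0.9, 0.5), tolerance = 1e-12)
  up <- update_posterior(tp$post, tp$stim, TRUE, tp$psy)
  expect_equal(up$mass, c(9 / 14, 5 / 14), tolerance = 1e-12)
  dn <- update_posterior(tp$post, tp$stim, FALSE, tp$psy)
  expect_equal(dn$mass, c(1 / 6, 5 / 6), tolerance = 1e-12)
  # identical response probabilities leave the posterior unchanged
  same <- two_point_posterior(c(0.7, 0.7))
  expect_equal(update_posterior(same$post, same$stim, TRUE, same$psy)$mass,
               c(0.5, 0.5), tolerance = 1e-12)
})

test_that("update_posterior matches the single-normalization Bayes oracle", {
  grid <- build_grid(3L, 3L, 3L, 3L)
  psy <- psychometric_config()
  set.seed(2024)
  for (i in 1:100) {
    prior <- runif(81); prior <- prior / sum(prior)
    post <- uniform_posterior(grid); post$mass <- prior
    stim <- stimulus(runif(1, 1, 30), runif(1, 0.01, 1))
    outcomes <- runif(3) < 0.5
    got <- update_posterior(post, stim, outcomes, psy)
    p <- response_probability(as_csf_params(grid$points), stim, psy)
    want <- oracle_bayes(prior, p, outcomes)
    expect_equal(got$mass, want, tolerance = 1e-12)
    expect_equal(sum(got$mass), 1, tolerance = 1e-12)
    expect_true(all(got$mass >= 0))
  }
})

test_that("expected information gain matches hand entropy computations", {
  tp <- two_point_posterior(c(0.9, 0.1))
  h <- function(p) -(p * log2(p) + (1 - p) * log2(1 - p))
  expect_equal(expected_information_gain(tp$post, tp$stim, tp$psy),
               1 - h(0.9), tolerance = 1e-10)
  # a barely informative stimulus yields strictly less
  weak <- two_point_posterior(c(0.6, 0.4))
  expect_lt(expected_information_gain(weak$post, weak$stim, weak$psy),
            expected_information_gain(tp$post, tp$stim, tp$psy))
  # degenerate posterior: nothing to learn from any stimulus
  deg <- tp$post; deg$mass <- c(1, 0)
  expect_equal(expected_information_gain(deg, tp$stim, tp$psy), 0)
  # nonnegative over random stimuli and posteriors
  grid <- build_grid(3L, 3L, 2L, 2L)
  set.seed(5)
  for (i in 1:20) {
    post <- uniform_posterior(grid)
    m <- runif(nrow(grid$points)); post$mass <- m / sum(m)
    gain <- expected_information_gain(
      post, stimulus(runif(1, 1, 30), runif(1, 0.01, 1)))
    expect_gte(gain, 0)
  }
})

test_that("select_stimulus is the argmax with first-index tie-break", {
  grid <- build_grid(4L, 3L, 2L, 2L)
  post <- uniform_posterior(grid)
  stims <- stimulus_grid(5L, 4L)
  sel <- select_stimulus(post, stims)
  gains <- vapply(seq_len(nrow(stims)), function(j)
    expected_information_gain(post, stimulus(stims$freq[j], stims$contrast[j])),
    numeric(1))
  expect_equal(attr(sel, "index"), which.max(gains))
  expect_equal(attr(sel, "gain"), max(gains), tolerance = 1e-12)
  # degenerate posterior: all gains zero, first stimulus wins
  post$mass <- c(1, rep(0, nrow(grid$points) - 1))
  expect_equal(attr(select_stimulus(post, stims), "index"), 1L)
  # single-candidate grid returns that stimulus
  one <- select_stimulus(uniform_posterior(grid), stims[3, ])
  expect_equal(one$freq, stims$freq[3])
  expect_error(select_stimulus(post, stims[0, ]), "empty")
})

test_that("posterior_feature_estimate is an expectation with central CI", {
  grid <- build_grid(2L, 2L, 2L, 2L)
  post <- uniform_posterior(grid)
  v <- seq_len(16)
  fe <- posterior_feature_estimate(post, v)
  expect_equal(fe$estimate, mean(v))
  expect_lte(fe$lower, 8); expect_gte(fe$upper, 9)  # brackets the median
  # two-point expectation
  post$mass <- c(0.5, 0.5, rep(0, 14))
  fe2 <- posterior_feature_estimate(post, c(1, 2, rep(0, 14)))
  expect_equal(fe2$estimate, 1.5)
  # degenerate posterior: point estimate, zero-width interval
  post$mass <- c(rep(0, 5), 1, rep(0, 10))
  fe3 <- posterior_feature_estimate(post, v)
  expect_equal(fe3$estimate, 6)
  expect_equal(fe3$lower, 6); expect_equal(fe3$upper, 6)
  expect_error(posterior_feature_estimate(post, v, credible_level = 1.2),
               "credible_level")
})

test_that("run_session is reproducible and records every trial", {
  eng <- tiny_engine()
  obs <- make_observer(csf_params(1.4, 2.5, 3.2, 0.4))
  s1 <- run_session(obs, eng, n_trials = 25, seed = 99)
  s2 <- run_session(obs, eng, n_trials = 25, seed = 99)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$estimates), 25)
  expect_equal(nrow(s1$letters), 25 * 3)
  expect_equal(sum(s1$mass), 1, tolerance = 1e-12)
  s3 <- run_session(obs, eng, n_trials = 25, seed = 100)
  expect_false(identical(s1$letters$correct, s3$letters$correct))
})

test_that("batched sessions agree with single sessions", {
  eng <- tiny_engine()
  set.seed(31)
  coh <- sample_cohort(cohort_spec("MS", 2, seed = 8))
  seeds <- c(101L, 202L, 303L, 404L)
  b <- run_sessions_batch(coh[, 4:7], eng, n_trials = 15, seeds = seeds,
                          record = "trajectory")
  for (i in seq_len(4)) {
    s <- run_session(make_observer(as_csf_params(coh[i, ]), eng$psy),
                     eng, n_trials = 15, seed = seeds[i])
    expect_equal(b$final$aulcsf[i], s$final$aulcsf, tolerance = 1e-10)
    expect_equal(b$final$csf_acuity[i], s$final$csf_acuity, tolerance = 1e-8)
    expect_equal(b$est[, i], s$estimates$aulcsf_est, tolerance = 1e-10)
    expect_equal(b$ci_lo[, i], s$estimates$ci_lo, tolerance = 1e-10)
  }
})

test_that("credible intervals tighten and the estimate converges", {
  eng <- tiny_engine()
  set.seed(77)
  coh <- sample_cohort(cohort_spec("MS", 15, seed = 21))[1:30, ]
  tru <- aulcsf(as_csf_params(coh))
  b <- run_sessions_batch(coh[, 4:7], eng, n_trials = 50,
                          seeds = 500 + seq_len(30), record = "trajectory")
  width <- b$ci_hi - b$ci_lo
  expect_lt(mean(width[50, ]), mean(width[5, ]))
  err <- abs(sweep(b$est, 2, tru))
  expect_lt(median(err[25, ]), median(err[5, ]))
  expect_lt(abs(median(err[25, ]) - median(err[50, ])), 0.05)
})
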