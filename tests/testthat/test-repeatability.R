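# COR, Bland-Altman, Mean Average Precision, paired bias, Welch's t.

test_that("COR matches hand computations and drops incomplete pairs", {
  expect_equal(as.numeric(coefficient_of_repeatability(1:4, 1:4)), 0)
  test <- c(1, 0, 1, 0); retest <- c(0, 1, 0, 1)   # differences +1,-1,+1,-1
  expect_equal(as.numeric(coefficient_of_repeatability(test, retest)),
               1.96 * sqrt(4 / 3), tolerance = 1e-12)
  co <- coefficient_of_repeatability(c(1, 2, NA, 4), c(1, 2, 3, NA))
  expect_equal(attr(co, "n_used"), 2)
  expect_equal(attr(co, "n_dropped"), 2)
  expect_error(coefficient_of_repeatability(c(1, NA), c(NA, 1)), "pairs")
})

test_that("COR recovers the closed form under Gaussian noise", {
  sigma <- 0.4
  for (s in 1:20) {
    set.seed(1000 + s)
    truth <- rnorm(500, 10, 3)
    co <- coefficient_of_repeatability(truth + rnorm(500, 0, sigma),
                                       truth + rnorm(500, 0, sigma))
    expect_equal(as.numeric(co), 1.96 * sqrt(2) * sigma, tolerance = 0.1)
  }
})

test_that("Bland-Altman summary obeys its identities", {
  # constant difference: zero-width limits
  ba <- bland_altman_summary(c(3, 4, 5), c(1, 2, 3))
  expect_equal(ba$bias, 2)
  expect_equal(ba$lower, 2); expect_equal(ba$upper, 2)
  ba2 <- bland_altman_summary(c(1, 0), c(0, 1))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$upper, 1.96 * sqrt(2), tolerance = 1e-12)
  # upper limit minus bias equals the COR, on arbitrary data
  set.seed(8)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(bland_altman_summary(x, y)$upper - bland_altman_summary(x, y)$bias,
               as.numeric(coefficient_of_repeatability(x, y)),
               tolerance = 1e-12)
})

test_that("MAP scores perfect identification, ties, and plain ranks", {
  # own retest strictly closest for every unit
  tests <- c(1, 5, 9, 14)
  expect_equal(as.numeric(mean_average_precision(tests, tests + 0.1)), 1)
  # two units, all four values identical: AP = (1 + 1/2)/2 each
  expect_equal(as.numeric(mean_average_precision(c(2, 2), c(2, 2))), 0.75)
  # three units, no ties; the third unit's own retest is beaten by the
  # second unit's retest (|20-19| < |20-30|), so it ranks second
  expect_equal(as.numeric(mean_average_precision(c(0, 10, 20),
                                                 c(0, 19, 30))),
               (1 + 1 + 1 / 2) / 3)
  expect_error(mean_average_precision(1, 2), "pairs")
})

test_that("MAP equals exhaustive tie enumeration on random small tables", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    # draw from few levels so ties are common
    tests <- sample(1:4, n, replace = TRUE)
    retests <- sample(1:4, n, replace = TRUE)
    expect_equal(as.numeric(mean_average_precision(tests, retests)),
                 oracle_map(tests, retests), tolerance = 1e-12)
  }
})

test_that("MAP is invariant under positive affine transforms", {
  set.seed(17)
  for (i in 1:20) {
    tests <- rnorm(15); retests <- rnorm(15)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(as.numeric(mean_average_precision(tests, retests)),
                 as.numeric(mean_average_precision(a * tests + b,
                                                   a * retests + b)),
                 tolerance = 1e-12)
  }
})

test_that("quantizing to nine chart-like levels lowers MAP", {
  # moderate within-unit noise, small against the chart's step width --
  # the regime in which a chart looks repeatable yet resolves poorly
  breaks <- seq(-0.15, 1.05, length.out = 10)
  levels9 <- function(x) breaks[pmin(9, pmax(1, findInterval(x, breaks)))]
  worse <- 0
  for (s in 1:100) {
    set.seed(3000 + s)
    truth <- runif(87, 0, 0.9)
    tests <- truth + rnorm(87, 0, 0.03)
    retests <- truth + rnorm(87, 0, 0.03)
    m_cont <- as.numeric(mean_average_precision(tests, retests))
    m_quant <- as.numeric(mean_average_precision(levels9(tests),
                                                 levels9(retests)))
    expect_lte(m_quant, m_cont + 1e-12)
    worse <- worse + (m_quant < m_cont)
  }
  expect_gte(worse, 95)
})

test_that("paired_bias reports bias, dispersion and degeneracy", {
  pb <- paired_bias(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pb$bias, 0); expect_equal(pb$abs_bias, 0)
  expect_equal(pb$t, 0); expect_equal(pb$p, 1)
  pb2 <- paired_bias(c(0.1, -0.1, 0.1, -0.1) + 5, rep(5, 4))
  expect_equal(pb2$bias, 0)
  expect_equal(pb2$abs_bias, 0.1)
  # constant nonzero difference: flagged, not an infinite t
  pb3 <- paired_bias(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_true(pb3$degenerate)
  expect_true(is.na(pb3$t))
  expect_error(paired_bias(1:3, 1:4), "equal length")
  # cross-check t against the reference implementation
  set.seed(2)
  x <- rnorm(30, 0.1); y <- rnorm(30)
  tt <- t.test(x - y)
  pb4 <- paired_bias(x, y)
  expect_equal(pb4$t, unname(tt$statistic))
  expect_equal(pb4$p, tt$p.value)
})

test_that("welch_t_test handles shifts and near-identical groups", {
  w0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0); expect_equal(w0$p, 1)
  w1 <- welch_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(mean(w1$ci), -1, tolerance = 1e-12)
  set.seed(4)
  w2 <- welch_t_test(rnorm(20, 0, 1e-3), rnorm(20, 1, 1e-3))
  expect_gt(abs(w2$t), 100)
  expect_lt(w2$p, 1e-10)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("repeatability_report aggregates per feature with exclusions", {
  tab <- data.frame(
    subject_id = rep(c("a", "b", "c"), 2), eye = "OD", group = "MS",
    feature = rep(c("aulcsf", "cs4"), each = 3),
    test = c(1, 2, 3, 5, NA, 7), retest = c(1.1, 2.2, 2.9, 5.1, 6, 7.2))
  rep <- repeatability_report(tab)
  expect_equal(rep$n_used, c(3, 2))
  expect_equal(rep$n_excluded, c(0, 1))
  expect_equal(rep$cor[1],
               as.numeric(coefficient_of_repeatability(c(1, 2, 3),
                                                       c(1.1, 2.2, 2.9))))
  expect_equal(rep$loa_upper - rep$bias, rep$cor, tolerance = 1e-12)
})
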