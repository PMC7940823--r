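# Test-retest repeatability and group-comparison statistics: Bland-Altman
# coefficient of repeatability, Mean Average Precision with exact tie
# handling, 25-vs-50-trial paired bias, Welch's t.

complete_pairs <- function(test, retest) {
  if (length(test) != length(retest)) stop("test/retest length mismatch")
  ok <- is.finite(test) & is.finite(retest)
  list(test = test[ok], retest = retest[ok], n_dropped = sum(!ok))
}

#' Bland-Altman coefficient of repeatability (COR)
#'
#' `COR = 1.96 * SD(test - retest)` with the sample (n-1) standard
#' deviation; incomplete pairs are dropped and counted.
#'
#' @param test,retest paired measurements; `NA` allowed.
#' @return The COR, with attributes `n_used` and `n_dropped`.
#' @export
coefficient_of_repeatability <- function(test, retest) {
  cp <- complete_pairs(test, retest)
  if (length(cp$test) < 2) stop("need at least 2 complete pairs")
  out <- 1.96 * stats::sd(cp$test - cp$retest)
  attr(out, "n_used") <- length(cp$test)
  attr(out, "n_dropped") <- cp$n_dropped
  out
}

#' Bland-Altman bias and limits of agreement
#'
#' Mean difference and mean +/- 1.96 SD.  The identity
#' `upper - bias = COR` holds on every input.
#'
#' @inheritParams coefficient_of_repeatability
#' @return A list `bias`, `lower`, `upper`, `n_used`, `n_dropped`.
#' @export
bland_altman_summary <- function(test, retest) {
  cp <- complete_pairs(test, retest)
  if (length(cp$test) < 2) stop("need at least 2 complete pairs")
  d <- cp$test - cp$retest
  m <- mean(d); s <- stats::sd(d)
  list(bias = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
       n_used = length(d), n_dropped = cp$n_dropped)
}

#' Mean Average Precision (MAP) of a test--retest table
#'
#' How uniquely a retest identifies its subject: for each unit, all
#' retests are ranked by similarity (absolute difference) to that unit's
#' test, and the precision is the reciprocal rank of the unit's own
#' retest.  Ties -- ubiquitous for quantized chart outcomes -- are scored
#' by the exact expected reciprocal rank under a uniform random ordering
#' of the tied block: with `m` candidates strictly closer and `k` tied
#' (own retest included), `AP = mean(1 / ((m+1):(m+k)))`.  MAP is the mean
#' AP over units and lies in (0, 1]; 1 means every unit's own retest is
#' strictly the closest (high precision and resolution), while heavily
#' tied, coarsely quantized outcomes are pulled toward 0.
#'
#' @param test,retest paired measurements; units with either member
#'   missing are excluded (counted in `n_dropped`).
#' @param symmetric also rank tests against each retest and average the
#'   two directions (default `FALSE`: queries are tests, candidates are
#'   retests).
#' @return MAP in (0, 1], with attributes `n_used` and `n_dropped`.
#' @export
mean_average_precision <- function(test, retest, symmetric = FALSE) {
  cp <- complete_pairs(test, retest)
  n <- length(cp$test)
  if (n < 2) stop("need at least 2 complete pairs")
  one_direction <- function(queries, candidates) {
    ap <- numeric(n)
    for (i in seq_len(n)) {
      d <- abs(queries[i] - candidates)
      m <- sum(d < d[i])
      k <- sum(d == d[i])
      ap[i] <- mean(1 / seq.int(m + 1L, m + k))
    }
    mean(ap)
  }
  out <- one_direction(cp$test, cp$retest)
  if (symmetric) out <- (out + one_direction(cp$retest, cp$test)) / 2
  attr(out, "n_used") <- n
  attr(out, "n_dropped") <- cp$n_dropped
  out
}

#' Paired bias between short- and long-test estimates
#'
#' Differences `d = estimates_short - estimates_long` summarized by mean
#' bias, mean absolute bias, SD, and a one-sample t-test of the mean
#' difference against zero.  A zero-variance nonzero-mean difference
#' vector is reported with `degenerate = TRUE` instead of an infinite t.
#'
#' @param estimates_short,estimates_long equal-length paired estimate
#'   vectors (e.g. after 25 and after 50 trials).
#' @return A list `bias`, `abs_bias`, `sd`, `t`, `df`, `p`, `n`,
#'   `degenerate`.
#' @export
paired_bias <- function(estimates_short, estimates_long) {
  if (length(estimates_short) != length(estimates_long))
    stop("paired vectors must have equal length")
  d <- estimates_short - estimates_long
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  s <- stats::sd(d)
  out <- list(bias = mean(d), abs_bias = mean(abs(d)), sd = s,
              t = NA_real_, df = n - 1L, p = NA_real_, n = n,
              degenerate = FALSE)
  if (s == 0) {
    if (mean(d) == 0) { out$t <- 0; out$p <- 1 } else out$degenerate <- TRUE
  } else {
    tt <- stats::t.test(d)
    out$t <- unname(tt$statistic); out$p <- tt$p.value
  }
  out
}

#' Welch's unequal-variance two-sample t-test
#'
#' Between-group comparison of a summary statistic (e.g. per-subject mean
#' AULCSF), with Welch-Satterthwaite degrees of freedom and a 95% CI of
#' the mean difference.
#'
#' @param group_a,group_b numeric vectors, each with at least 2 values.
#' @return A list `t`, `df`, `p`, `ci` (95% CI of mean(a) - mean(b)),
#'   `mean_diff`.
#' @export
welch_t_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  tt <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       ci = unname(tt$conf.int), mean_diff = mean(group_a) - mean(group_b))
}

#' Repeatability report for a long test--retest table
#'
#' Computes COR, Bland-Altman bias/limits and MAP per feature of a table
#' as produced by [simulate_test_retest()] (long format with columns
#' `feature`, `test`, `retest`).
#'
#' @param table long-format test-retest data.frame.
#' @return A data.frame with one row per feature: `feature`, `cor`,
#'   `bias`, `loa_lower`, `loa_upper`, `map`, `n_used`, `n_excluded`.
#' @export
repeatability_report <- function(table) {
  feats <- unique(table$feature)
  rows <- lapply(feats, function(f) {
    sub <- table[table$feature == f, , drop = FALSE]
    cor_v <- coefficient_of_repeatability(sub$test, sub$retest)
    ba <- bland_altman_summary(sub$test, sub$retest)
    map_v <- mean_average_precision(sub$test, sub$retest)
    data.frame(feature = f, cor = as.numeric(cor_v), bias = ba$bias,
               loa_lower = ba$lower, loa_upper = ba$upper,
               map = as.numeric(map_v),
               n_used = attr(cor_v, "n_used"),
               n_excluded = attr(cor_v, "n_dropped"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
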