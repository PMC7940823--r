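# Discretization of the CSF parameter space and of the stimulus space.

#' Discretized CSF parameter grid
#'
#' Builds the Cartesian product of four axes carrying the posterior mass.
#' Peak gain is linear in log10 sensitivity (i.e. sensitivity is
#' log-spaced); peak frequency, bandwidth and truncation axes are
#' log-spaced over their ranges.  Defaults span the literature-typical
#' ranges: sensitivity 2--2000 (30 values), peak frequency 0.2--20 cpd
#' (20), bandwidth 1--9 octaves (15), truncation 0.02--2 log10 units (10),
#' for 90,000 grid points.
#'
#' @param gain_count,freq_count,bw_count,trunc_count points per axis,
#'   each at least 2.
#' @param gain_range range of peak contrast *sensitivity* (not log units).
#' @param freq_range range of peak frequency, cpd.
#' @param bw_range range of bandwidth, octaves.
#' @param trunc_range range of the truncation drop, log10 units.
#' @return An object of class `param_grid` with `axes` (named list of the
#'   four increasing axes; `peak_gain` in log10 units) and `points` (a
#'   data.frame with one row per grid point).
#' @export
build_grid <- function(gain_count = 30L, freq_count = 20L, bw_count = 15L,
                       trunc_count = 10L,
                       gain_range = c(2, 2000), freq_range = c(0.2, 20),
                       bw_range = c(1, 9), trunc_range = c(0.02, 2)) {
  counts <- c(gain_count, freq_count, bw_count, trunc_count)
  if (any(counts < 2)) stop("each axis needs at least 2 points")
  check_range <- function(r, nm) {
    if (!(length(r) == 2 && r[1] > 0 && r[1] < r[2]))
      stop("invalid range for ", nm, ": need 0 < min < max")
  }
  check_range(gain_range, "gain"); check_range(freq_range, "freq")
  check_range(bw_range, "bandwidth"); check_range(trunc_range, "truncation")
  log_axis <- function(r, n) 10^seq(log10(r[1]), log10(r[2]), length.out = n)
  axes <- list(
    peak_gain = seq(log10(gain_range[1]), log10(gain_range[2]),
                    length.out = gain_count),
    peak_freq = log_axis(freq_range, freq_count),
    bandwidth = log_axis(bw_range, bw_count),
    truncation = log_axis(trunc_range, trunc_count)
  )
  points <- expand.grid(peak_gain = axes$peak_gain,
                        peak_freq = axes$peak_freq,
                        bandwidth = axes$bandwidth,
                        truncation = axes$truncation,
                        KEEP.OUT.ATTRS = FALSE)
  structure(list(axes = axes, points = points), class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat("CSF parameter grid:",
      paste(vapply(x$axes, length, 1L), collapse = " x "),
      "=", nrow(x$points), "points\n")
  invisible(x)
}

#' Candidate stimulus grid
#'
#' Log-spaced spatial frequencies crossed with log-spaced Michelson
#' contrasts; the adaptive engine picks the most informative member each
#' trial.  Defaults: 24 frequencies over 1--36 cpd x 30 contrasts over
#' 0.002--1.
#'
#' @param freq_count,contrast_count points per dimension.
#' @param freq_range frequency range, cpd.
#' @param contrast_range contrast range, within (0, 1].
#' @return A data.frame with columns `freq` and `contrast`, frequency
#'   varying fastest.
#' @export
stimulus_grid <- function(freq_count = 24L, contrast_count = 30L,
                          freq_range = c(1, 36),
                          contrast_range = c(0.002, 1)) {
  if (freq_count < 1 || contrast_count < 1) stop("counts must be positive")
  if (contrast_range[2] > 1) stop("contrast cannot exceed 1")
  f <- 10^seq(log10(freq_range[1]), log10(freq_range[2]),
              length.out = freq_count)
  ctr <- 10^seq(log10(contrast_range[1]), log10(contrast_range[2]),
                length.out = contrast_count)
  expand.grid(freq = f, contrast = ctr, KEEP.OUT.ATTRS = FALSE)
}
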