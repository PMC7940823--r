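# Truncated log-parabola contrast sensitivity function (CSF) and its
# scalar features.  All sensitivities are log10 units; frequencies are
# cycles per degree (cpd).

#' CSF parameter set
#'
#' The contrast sensitivity function is modelled as a log-parabola in
#' log10(frequency) with a low-frequency truncation plateau:
#' peak gain (log10 sensitivity at the peak), peak spatial frequency (cpd),
#' full width at half maximum (octaves), and the drop from the peak to the
#' low-frequency plateau (log10 units).
#'
#' All fields may be vectors (recycled to common length), so a single
#' object can describe a whole cohort of observers.
#'
#' @param peak_gain log10 contrast sensitivity at the peak.
#' @param peak_freq peak spatial frequency, cpd; must be positive.
#' @param bandwidth full width at half maximum, octaves; must be positive.
#' @param truncation low-frequency plateau drop, log10 units; must be >= 0.
#' @return An object of class `csf_params` with the four fields as
#'   equal-length numeric vectors.
#' @export
#' @examples
#' p <- csf_params(peak_gain = 1.5, peak_freq = 3, bandwidth = 4, truncation = 0.5)
#' log_sensitivity(p, 3)
csf_params <- function(peak_gain, peak_freq, bandwidth, truncation) {
  n <- max(length(peak_gain), length(peak_freq), length(bandwidth),
           length(truncation))
  peak_gain  <- rep_len(as.numeric(peak_gain), n)
  peak_freq  <- rep_len(as.numeric(peak_freq), n)
  bandwidth  <- rep_len(as.numeric(bandwidth), n)
  truncation <- rep_len(as.numeric(truncation), n)
  if (any(!is.finite(peak_freq)) || any(peak_freq <= 0))
    stop("peak_freq must be positive and finite")
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0))
    stop("bandwidth must be positive and finite")
  if (any(!is.finite(truncation)) || any(truncation < 0))
    stop("truncation must be >= 0")
  structure(list(peak_gain = peak_gain, peak_freq = peak_freq,
                 bandwidth = bandwidth, truncation = truncation),
            class = "csf_params")
}

#' @export
print.csf_params <- function(x, ...) {
  cat("CSF parameters (", length(x$peak_gain), " observer",
      if (length(x$peak_gain) != 1) "s", "):\n", sep = "")
  print(data.frame(peak_gain = x$peak_gain, peak_freq = x$peak_freq,
                   bandwidth = x$bandwidth, truncation = x$truncation),
        ...)
  invisible(x)
}

# Coerce a data.frame with the four parameter columns to csf_params.
as_csf_params <- function(x) {
  if (inherits(x, "csf_params")) return(x)
  csf_params(x$peak_gain, x$peak_freq, x$bandwidth, x$truncation)
}

#' Spatial frequency band
#'
#' The band over which the area under the log CSF is integrated.
#' Defaults to 1.5--18 cpd.
#'
#' @param f_min,f_max band limits in cpd, `0 < f_min < f_max`.
#' @return An object of class `freq_band`.
#' @export
freq_band <- function(f_min = 1.5, f_max = 18) {
  if (!(is.finite(f_min) && is.finite(f_max) && f_min > 0 && f_min < f_max))
    stop("need 0 < f_min < f_max")
  structure(list(f_min = f_min, f_max = f_max), class = "freq_band")
}

#' Log10 contrast sensitivity of the truncated log-parabola CSF
#'
#' For `f >= peak_freq` the value is the log-parabola
#' `G - kappa * ((log10 f - log10 f_peak) / (0.5 * beta * log10 2))^2`
#' with `kappa = log10 2` (so the curve drops exactly half an order of a
#' factor-of-two -- i.e. `log10 2` -- at half a bandwidth from the peak).
#' Below the peak the curve cannot fall under the plateau `G - delta`.
#' Values may be negative (sensitivity below 1, contrast threshold above
#' 100%).
#'
#' @param params a [csf_params()] object (fields may be vectors).
#' @param freq spatial frequency, cpd; positive; recycled against `params`.
#' @return Numeric vector of log10 sensitivities.
#' @export
log_sensitivity <- function(params, freq) {
  params <- as_csf_params(params)
  if (any(!is.finite(freq)) || any(freq <= 0))
    stop("freq must be positive and finite")
  n <- max(length(params$peak_gain), length(freq))
  g  <- rep_len(params$peak_gain, n)
  fp <- rep_len(params$peak_freq, n)
  bw <- rep_len(params$bandwidth, n)
  dl <- rep_len(params$truncation, n)
  f  <- rep_len(as.numeric(freq), n)
  kappa <- log10(2)
  half_width <- 0.5 * bw * kappa
  dev <- (log10(f) - log10(fp)) / half_width
  s <- g - kappa * dev * dev
  low <- f < fp
  if (any(low)) s[low] <- pmax(s[low], (g - dl)[low])
  s
}

#' Highest frequency at which sensitivity reaches a criterion
#'
#' Closed-form cutoff on the descending branch of the log-parabola:
#' `log10 f = log10 f_peak + (0.5 * beta * log10 2) * sqrt((G - t) / log10 2)`
#' when the peak gain reaches the criterion `t`; `NA` otherwise (the eye
#' never attains the required sensitivity -- a real outcome, mirrored by
#' excluding such eyes from low-contrast features rather than scoring 0).
#'
#' `threshold = 0` gives the CSF acuity (100% contrast needed);
#' `threshold = log10(4)` gives the 25%-contrast cutoff CS4.
#'
#' @param params a [csf_params()] object.
#' @param threshold required log10 sensitivity; recycled.
#' @return Frequency in cpd, or `NA` where the criterion is never reached.
#' @export
cutoff_frequency <- function(params, threshold) {
  params <- as_csf_params(params)
  n <- max(length(params$peak_gain), length(threshold))
  g  <- rep_len(params$peak_gain, n)
  fp <- rep_len(params$peak_freq, n)
  bw <- rep_len(params$bandwidth, n)
  t  <- rep_len(as.numeric(threshold), n)
  kappa <- log10(2)
  out <- rep(NA_real_, n)
  ok <- g >= t
  if (any(ok)) {
    lf <- log10(fp[ok]) + 0.5 * bw[ok] * kappa * sqrt((g[ok] - t[ok]) / kappa)
    out[ok] <- 10^lf
  }
  out
}

#' Area under the log CSF (AULCSF)
#'
#' Trapezoidal integral of `max(log_sensitivity, 0)` over log10 frequency
#' on `n_grid` log-spaced points across the band.  Clipping the integrand
#' at zero keeps the area nonnegative and comparable across severely
#' impaired observers, for whom portions of the curve fall below a
#' sensitivity of 1.
#'
#' @param params a [csf_params()] object; vector fields give one area per
#'   observer.
#' @param band a [freq_band()]; defaults to 1.5--18 cpd.
#' @param n_grid number of integration nodes, at least 50 (default 500).
#' @return Numeric vector of areas (log10-sensitivity x log10-frequency
#'   units), nonnegative.
#' @export
aulcsf <- function(params, band = freq_band(), n_grid = 500L) {
  params <- as_csf_params(params)
  if (!inherits(band, "freq_band")) stop("band must be a freq_band")
  if (n_grid < 50) stop("n_grid must be at least 50")
  lf <- seq(log10(band$f_min), log10(band$f_max), length.out = n_grid)
  f <- 10^lf
  n <- length(params$peak_gain)
  kappa <- log10(2)
  half_width <- 0.5 * params$bandwidth * kappa
  # n x n_grid matrix of clipped log sensitivities
  dev <- outer(-log10(params$peak_freq), lf, "+") / half_width
  s <- params$peak_gain - kappa * dev * dev
  plateau <- params$peak_gain - params$truncation
  low <- outer(params$peak_freq, f, ">")
  if (any(low)) {
    plm <- matrix(plateau, n, n_grid)
    s[low] <- pmax(s[low], plm[low])
  }
  s[s < 0] <- 0
  dx <- (lf[n_grid] - lf[1]) / (n_grid - 1)
  dx * (rowSums(s) - 0.5 * (s[, 1] + s[, n_grid]))
}

#' Scalar CSF features
#'
#' Computes the features used as clinical outcomes: the AULCSF, the CSF
#' acuity (cutoff frequency at 100% contrast, i.e. log sensitivity 0), and
#' cutoff frequencies for a set of stimulus contrasts (criterion
#' `log10(1/c)` for contrast `c`).  The 25% contrast cutoff is the CS4
#' feature; by default its criterion is `log10(4)`, with `cs4_threshold`
#' allowing the rounded value 0.6 instead.
#'
#' @param params a [csf_params()] object (scalar fields).
#' @param band a [freq_band()] for the AULCSF.
#' @param contrast_levels Michelson contrasts in (0, 1]; defaults to 2.5%
#'   and 5% steps from 5% to 50%.
#' @param cs4_threshold log10 sensitivity criterion used for the CS4
#'   feature (default `log10(4)`).
#' @return A list of class `csf_features`: `aulcsf`, `csf_acuity`,
#'   `cs_cutoffs` (named by contrast, `NA` where the criterion is never
#'   met), and `cs4`.
#' @export
features_from_params <- function(params, band = freq_band(),
                                 contrast_levels = c(0.025, seq(0.05, 0.50, by = 0.05)),
                                 cs4_threshold = log10(4)) {
  params <- as_csf_params(params)
  if (length(params$peak_gain) != 1L)
    stop("features_from_params expects a single observer")
  cl <- as.numeric(contrast_levels)
  if (any(cl <= 0) || any(cl > 1)) stop("contrast levels must lie in (0, 1]")
  cuts <- cutoff_frequency(params, log10(1 / cl))
  names(cuts) <- as.character(cl)
  structure(list(
    aulcsf = aulcsf(params, band),
    csf_acuity = cutoff_frequency(params, 0),
    cs_cutoffs = cuts,
    cs4 = cutoff_frequency(params, cs4_threshold)
  ), class = "csf_features")
}
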