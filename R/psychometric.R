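# Per-letter psychometric model of a simulated observer.

#' Psychometric response model configuration
#'
#' Per-letter probability of a correct response follows a log-Weibull
#' psychometric function with a guessing floor and a lapse ceiling.  With
#' 10 Sloan letter alternatives the guess rate is 0.1; the lapse rate
#' (attention failures at easy stimuli) defaults to 0.04 and the Weibull
#' slope to 3.5, the steepness typical of letter-identification
#' psychometric functions.  The function is anchored so that a stimulus at the
#' observer's contrast threshold is seen exactly half the time (before
#' guesses and lapses).
#'
#' @param guess guessing rate, `0 <= guess < 1` (default `1/alternatives`).
#' @param lapse lapse rate, `0 <= lapse < 1`, `guess + lapse < 1`.
#' @param slope Weibull slope, positive.
#' @param letters_per_trial letters shown per adaptive trial (default 3,
#'   all at the same size and contrast).
#' @param alternatives number of response alternatives (default 10 Sloan
#'   letters).
#' @return An object of class `psy_config`.
#' @export
psychometric_config <- function(guess = 1 / alternatives, lapse = 0.04,
                                slope = 3.5, letters_per_trial = 3L,
                                alternatives = 10L) {
  if (!(guess >= 0 && guess < 1 && lapse >= 0 && lapse < 1 &&
        guess + lapse < 1))
    stop("need 0 <= guess < 1, 0 <= lapse < 1, guess + lapse < 1")
  if (slope <= 0) stop("slope must be positive")
  if (letters_per_trial < 1) stop("letters_per_trial must be >= 1")
  structure(list(guess = guess, lapse = lapse, slope = slope,
                 letters_per_trial = as.integer(letters_per_trial),
                 alternatives = as.integer(alternatives)),
            class = "psy_config")
}

#' Stimulus: a letter size (spatial frequency) and contrast
#'
#' @param freq spatial frequency in cpd, positive.
#' @param contrast Michelson contrast in (0, 1].
#' @return An object of class `stimulus`.
#' @export
stimulus <- function(freq, contrast) {
  if (any(freq <= 0)) stop("freq must be positive")
  if (any(contrast <= 0) || any(contrast > 1))
    stop("contrast must lie in (0, 1]")
  structure(list(freq = as.numeric(freq), contrast = as.numeric(contrast)),
            class = "stimulus")
}

#' Per-letter probability of a correct response
#'
#' `p = guess + (1 - guess - lapse) * F` with
#' `F = 1 - exp(-ln 2 * (c / tau)^slope)` and contrast threshold
#' `tau = 10^(-log_sensitivity(params, freq))`, so that `F(tau) = 1/2`.
#'
#' @param params a [csf_params()] object; vector fields give one
#'   probability per observer.
#' @param stim a [stimulus()] (scalar fields) or anything with `freq` and
#'   `contrast` components.
#' @param psy a [psychometric_config()].
#' @return Probability (or vector of probabilities) in
#'   `[guess, 1 - lapse]`.
#' @export
response_probability <- function(params, stim, psy = psychometric_config()) {
  tau <- 10^(-log_sensitivity(params, stim$freq))
  f <- 1 - exp(-log(2) * (stim$contrast / tau)^psy$slope)
  psy$guess + (1 - psy$guess - psy$lapse) * f
}
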