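# Independent brute-force oracles used to pin down expected values.
# Each is written directly from the mathematical definition and shares no
# code with the implementation it checks.

# Riemann-midpoint quadrature of the clipped log CSF over log10 frequency
oracle_aulcsf <- function(g, fp, bw, dl, f_min = 1.5, f_max = 18,
                          n = 1e5) {
  kappa <- log10(2)
  lf <- seq(log10(f_min), log10(f_max), length.out = n + 1)
  mid <- (lf[-1] + lf[-(n + 1)]) / 2
  s <- vapply(mid, function(x) {
    par <- g - kappa * ((x - log10(fp)) / (0.5 * bw * kappa))^2
    if (10^x < fp) par <- max(par, g - dl)
    max(par, 0)
  }, numeric(1))
  sum(s) * (lf[2] - lf[1])
}

# single-normalization Bayes update: explicit likelihood product over all
# letter outcomes, normalized once
oracle_bayes <- function(prior, p_correct, outcomes) {
  lik <- rep(1, length(prior))
  for (ok in outcomes) lik <- lik * (if (ok) p_correct else 1 - p_correct)
  post <- prior * lik
  post / sum(post)
}

# all permutations of a vector (n <= 7)
oracle_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in oracle_permutations(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

# MAP by exhaustive enumeration: for each query, average the reciprocal
# rank of its own retest over every ordering of the tied candidates
oracle_map <- function(tests, retests) {
  n <- length(tests)
  ap <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(tests[i] - retests)
    closer <- sum(d < d[i])
    tied <- which(d == d[i])      # includes i
    perms <- oracle_permutations(tied)
    rr <- vapply(perms, function(p) 1 / (closer + which(p == i)), numeric(1))
    ap[i] <- mean(rr)
  }
  mean(ap)
}

# tiny engine shared across tests (kept deliberately small for speed)
tiny_engine <- function(psy = psychometric_config()) {
  qcsf_engine(grid = build_grid(6L, 5L, 3L, 2L),
              stimuli = stimulus_grid(8L, 6L),
              psy = psy)
}
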