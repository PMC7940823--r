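---
title: "Simulating quantitative contrast-sensitivity testing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating quantitative contrast-sensitivity testing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qcsfsim)
```

`qcsfsim` rebuilds, entirely in silico, the chain of measurement and
analysis used to validate adaptive contrast-sensitivity testing as a
clinical vision outcome: observers with known contrast sensitivity
functions, a Bayesian adaptive testing engine, a quantized acuity chart,
and the precision, repeatability and discrimination analyses run on top.
This vignette explains the models, the parameters that matter, the
calibration of the synthetic cohorts, and the numerical choices — and
what the simulations can and cannot say about real patient data.

## The CSF model

Contrast sensitivity as a function of spatial frequency $f$ (cycles per
degree) is modelled as a truncated log-parabola in log-log space,

$$S(f) = G - \kappa\left(\frac{\log_{10} f - \log_{10} f_0}
{\tfrac{1}{2}\beta\,\log_{10} 2}\right)^{\!2},\qquad \kappa = \log_{10} 2,$$

with the low-frequency branch bounded below by a plateau $G-\delta$.
The four parameters are the peak gain $G$ (log10 sensitivity), peak
frequency $f_0$ (cpd), bandwidth $\beta$ (full width at half maximum, in
octaves — hence the fixed $\kappa$: half a bandwidth from the peak the
curve has dropped by exactly $\log_{10}2$), and truncation $\delta$
(log10 units). This is the standard four-parameter description used by
adaptive CSF devices; the parameterization maps one-to-one onto the
quantities the clinical literature reports.

Scalar features:

* `aulcsf()` — trapezoidal integral of $\max(S,0)$ over $\log_{10} f$
  from 1.5 to 18 cpd. The integrand is clipped at zero so that
  sensitivities below 1 (contrast thresholds above 100%, physically
  unreachable) contribute nothing; this keeps the area nonnegative and
  comparable across severely impaired observers. Whether a hardware
  device clips before integrating is not documented anywhere we know of;
  clipping is this package's choice and is applied consistently to truth
  and estimate, so comparisons are unaffected.
* `cutoff_frequency()` — closed-form inverse of the descending branch;
  threshold 0 gives the CSF acuity, threshold $\log_{10}4 \approx 0.602$
  the 25%-contrast cutoff CS4. An observer whose peak gain never reaches
  the criterion yields an explicit missing value — never a zero — which
  propagates through every downstream table, mirroring how low-vision
  eyes are excluded from low-contrast features rather than scored. The
  exact criterion is $\log_{10}4$ by default; `cs4_threshold = 0.6`
  reproduces the rounded convention.

## The psychometric model and the adaptive engine

A presented letter at frequency $f$ and Michelson contrast $c$ is
identified correctly with probability

$$p = \gamma + (1-\gamma-\lambda)\left[1 -
\exp\!\left(-\ln 2\,(c/\tau(f))^{\eta}\right)\right],
\qquad \tau(f) = 10^{-S(f)},$$

a log-Weibull anchored so a stimulus at threshold contrast is seen half
the time before guesses and lapses. Defaults: guess rate $\gamma = 0.1$
(ten Sloan alternatives), lapse rate $\lambda = 0.04$, slope
$\eta = 3.5$. The slope deserves a note: shallow slopes (near 2) make
simulated observers substantially noisier than the within-visit
variability actually reported for adaptive CSF testing in patients;
$\eta = 3.5$, a typical steepness for letter identification, reproduces
the reported magnitudes (chart coefficients of repeatability near one
line, 25-vs-50-trial mean absolute bias below 0.05 log10 units). All
values are configurable through `psychometric_config()`.

The engine (`qcsf_engine()`, `run_session()`) maintains a posterior over
a discretized 4-D parameter grid, initialized uniform (the device prior
is unpublished). Each trial it scores every candidate stimulus by the
expected one-letter information gain
$I = H(\bar p) - \sum_i m_i H(p_i)$ (binary entropy, bits) and presents
the argmax — ties broken by grid order for determinism — as three
letters at the same size and contrast, each an independent Bernoulli
outcome, with a per-letter Bayes update. The lookahead is one letter
rather than the full three-letter trial: the greedy one-step criterion
is the standard tractable choice and the three posterior updates per
trial recover most of the difference. The reported scalar estimate is
the posterior mean of the feature over the grid (marginalizing the full
joint posterior), with a central 68.3% mass-weighted credible interval;
an alternative would be the feature of the posterior-mean parameters,
but marginalizing the feature respects its nonlinearity in the
parameters.

`run_sessions_batch()` runs a whole cohort's sessions in lockstep with
matrix algebra; each session's response stream is pre-drawn from its own
seed, so batched and single runs agree to floating-point rounding and
results never depend on batch composition.

### Numerical choices

* Default parameter grid: $12 \times 10 \times 6 \times 5$ points
  (gain over sensitivity 2–2000, log-spaced; peak frequency 0.2–20 cpd;
  bandwidth 1–9 octaves; truncation 0.02–2), 3600 points; default
  stimulus grid $15 \times 13$ (1–36 cpd by 0.002–1 contrast). This
  compact profile is what all shipped experiments and tests use; it
  keeps a cohort-scale Monte-Carlo study in the minutes range while its
  residual estimate noise (AULCSF SD ≈ 0.07 at 25 trials) sits inside
  the range reported for patients. A literature-scale
  $30 \times 20 \times 15 \times 10$ grid remains one `build_grid()`
  call away; estimates sharpen modestly at ~25× the memory and compute.
* AULCSF integration: 500 log-spaced trapezoid nodes by default
  (agreement with a $10^5$-point quadrature oracle to $10^{-4}$;
  `n_grid` below 50 is refused).
* Posterior normalization after every letter; with $\gamma,\lambda > 0$
  the likelihood is bounded away from 0/1 and the mass cannot vanish.
* Degenerate inputs are contracts, not crashes: zero-variance paired
  differences are flagged rather than yielding infinite t statistics;
  missing features are dropped per-metric with counts logged.

## The synthetic cohorts

`cohort_spec()` / `sample_cohort()` draw per-eye true parameters from
independent Gaussians in transformed space (identity scale for gain and
truncation, log10 for peak frequency and bandwidth), with a
subject-level random effect giving a between-eye correlation of 0.7 by
default. Two cohort layouts mirror the validation designs: 54 subjects
with two monocular subjects and one technical exclusion (105
measurements) for convergence, and 44 subjects with one single-eye
subject (87 test–retest pairs) for repeatability; eyes are the analysis
units for those two, subjects (eye-averaged) for discrimination.

Two generator-level calibrations tie the synthetic cohorts to the
published patient summaries rather than to arbitrary choices:

* **Location.** `calibrate_group_location()` bisects the gain location
  until the Monte-Carlo mean *true* AULCSF of the generating
  distribution (4000 draws, fixed internal seed, so the objective is
  deterministic and monotone) hits the target — 1.21 for the impaired
  group, 1.42 for controls in the shipped discrimination experiment.
* **Dispersion.** The scale parameters (gain 0.09, log-frequency 0.07,
  log-bandwidth 0.055, truncation 0.07) were set so the subject-level
  true AULCSF SD is ≈ 0.14, which is what the published group
  comparison implies (a Welch statistic near 4.8 with a 0.21 group gap
  at 13 vs 61 subjects requires a subject SD near 0.15 including
  measurement noise). Wider, uncalibrated spreads would make the
  simulated discrimination analysis unrealistically underpowered.

Test–retest variability arises from response stochasticity alone by
default (`retest_jitter_sd = 0`): within a single visit the true CSF is
taken as stable, so whatever disagreement the features show is
measurement noise — exactly the quantity the repeatability metrics are
meant to isolate.

The chart simulation (`simulate_va500()`) reads a nine-line Snellen
chart top-down; each line maps to its optotype stroke frequency
($30/10^{\mathrm{LogMAR}}$ cpd, the standard convention) at full
contrast, letters per line default to 1–10 from largest to smallest
(charts differ; it is configurable), and the outcome is the lowest
LogMAR line with fewer than two mistakes — read literally, plus a
one-correct-letter guard so a wholly failed single-letter line cannot
qualify. Chart reading is self-paced, so its per-letter lapse rate
defaults to 0.01 rather than the adaptive test's 0.04; with the brief
-presentation lapse rate the simulated chart repeatability is about
twice what high-contrast charts actually show. The output is quantized
to exactly nine values while the qCSF features are continuous — that
asymmetry is the mechanism the repeatability experiment exploits.

## The statistics

* `coefficient_of_repeatability()`: $1.96\times$ the ($n-1$) SD of
  test-minus-retest differences; `bland_altman_summary()` supplies bias
  and limits of agreement, with `upper − bias = COR` holding identically.
* `mean_average_precision()`: every retest is ranked by absolute
  difference to a given subject's test; the subject's average precision
  is the reciprocal rank of their own retest, and ties — the normal case
  for chart data — are scored by the exact expectation of the reciprocal
  rank under a uniform random ordering of the tied block:
  $\mathrm{AP} = \frac{1}{k}\sum_{r=m+1}^{m+k} 1/r$ with $m$ strictly
  closer and $k$ tied candidates. Queries are tests and candidates are
  retests (a symmetrized variant is available via `symmetric = TRUE`).
  Similarity is absolute difference on the feature's native scale; MAP
  is invariant under common positive affine transforms, so units cancel,
  but it is not invariant under nonlinear rescaling — a documented
  convention, as is the tie rule.
* `paired_bias()` (25-vs-50-trial convergence) and `welch_t_test()`
  (group discrimination) delegate the t machinery to `stats::t.test`.

## What the experiments show — and what they cannot

The three drivers under `analysis/` are pure functions of
`(configuration, seed)`; rerunning one reproduces its output
byte-for-byte, and all CSV tables round-trip through the package's own
readers. Shipped problem sizes: 105 fifty-trial sessions (convergence),
87 pairs × two sessions plus two chart readings (repeatability;
100-replicate versions of this and the next run in the acceptance
tests), 148 sessions across 74 subjects (discrimination).

Passing these simulations demonstrates internal validity: the engine
converges on observers of the assumed family, the metrics behave as
designed, quantization produces the COR/MAP reversal, and calibrated
group differences are detectable at the stated sample sizes. They do not
demonstrate external validity. Real eyes need not follow a truncated
log-parabola; real response errors are not exchangeable Bernoulli trials
(fatigue, learning, criterion shifts); the commercial device's prior,
grids and lookahead are unpublished and surely differ in detail; chart
reading in the clinic involves encouragement and termination rules
richer than the simulated stopping criterion. Test-duration analyses,
optic-neuritis subgroups and structural (OCT) correlates are outside the
package's scope.

## Known limitations

* The coarse default grid quantizes the posterior; estimates carry a
  mild shrinkage toward the grid interior (visible as a small negative
  mean bias in the convergence summary). Comparative conclusions are
  insensitive to it, absolute feature values less so.
* CS4 estimates are reported missing when the posterior puts less than
  half its mass on the criterion being attainable; near that boundary
  the estimate is unstable by construction.
* Cutoff-frequency features have heavy upper tails on coarse grids
  (wide-bandwidth, high-gain grid points imply extreme extrapolated
  cutoffs), which inflates their COR in cpd units; their MAP, being
  rank-based, is unaffected.
* MAP's tie convention (exact expected reciprocal rank) is one of
  several in the ranking literature; alternatives shift absolute MAP
  values slightly but preserve the quantized-vs-continuous ordering.
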