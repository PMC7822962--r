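---
title: "Mixture models of misreport errors in visual crowding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture models of misreport errors in visual crowding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdmix)
```

## The problem

In a continuous-report crowding experiment an observer estimates the
orientation of a peripheral Gabor target that may be surrounded by flanker
Gabors on the horizontal meridian. Orientation lives on a 180-degree
periodic circle, and the quantity analysed is the signed estimation error
`theta = response - target`, wrapped to `(-90, +90]`. Crowding shows up in
this error distribution in three distinguishable ways: broader report noise
around the target, more uniform guessing, and **misreports** — trials on
which the observer reproduces a flanker's orientation instead of the
target's. `crowdmix` implements the mixture models that separate these
sources and quantify the *inner-outer asymmetry*: whether the flanker more
eccentric than the target (the outer flanker) captures reports more often
than the one closer to fixation.

## The models

All densities are per degree of orientation on the 180-periodic circle.
Report noise is a von Mises distribution on the angle-doubled circle with
shared variability `sigma` (degrees); `f(theta)` below denotes that density
with mean zero, and `f(theta - theta*_i)` the same density centred on
flanker *i*'s offset `theta*_i = flanker_i - target`.

* **S — standard mixture** (2 parameters `gamma`, `sigma`):
  `p(theta) = (1 - gamma) f(theta) + gamma/180`.
* **M — misreport** (3: `gamma`, `sigma`, `beta`): adds a pooled misreport
  component, `beta` split equally over the `m` flankers:
  `+ beta (1/m) sum_i f(theta - theta*_i)`.
* **2M / 4M — independent misreport** (4 / 6 parameters): one weight per
  flanker (`beta_1I`, `beta_1O`; or `beta_2I`, `beta_1I`, `beta_1O`,
  `beta_2O`). These are the models whose fitted weights expose the
  inner-outer asymmetry.
* **2B / 4B — with bias** (5 / 7 parameters): 2M/4M plus a mean shift `mu`
  of the *target* component, fitted on outward-realigned errors, testing
  whether an additional averaging-toward-the-outer-flanker process is
  needed beyond asymmetric misreport weights.

The target weight is always `P_T = 1 - gamma - sum(beta)`, the probability
of reporting the target itself. The pooled model M is exactly the
equal-weights special case of 2M/4M, giving the nesting chain
S ⊂ M ⊂ 2M/4M ⊂ 2B/4B that the AICc comparison exploits.

### Design choices in the model layer

Several details are not pinned down by the verbal description of this model
family; the package resolves them as follows.

* **Angle doubling.** 180-periodicity is handled by the standard
  orientation-statistics convention `theta -> 2 theta`, keeping each
  component a true von Mises. `sigma` is the circular SD of the
  doubled-angle distribution mapped back to orientation degrees
  (`sigma = (90/pi) sqrt(-2 log(I1(kappa)/I0(kappa)))`), so fitted values
  are directly comparable to plotted error SDs in the 10–20 degree range.
* **Boundary convention.** Errors live in `(-90, +90]`; `-90` is reported
  as `+90`. Any half-open convention works as long as it is fixed;
  `wrap_error()` documents and enforces this one.
* **Guess term.** The uniform component is `1/180` per degree for every
  model. (Descriptions of this family sometimes write `1/n` with `n` the
  number of feature values; with 180 orientation values the two coincide.)
* **Bias parameterisation.** In 2B/4B, `mu` shifts the mean of the target
  component only; flanker components stay centred on their observed
  offsets. This is the minimal model of a mean bias toward the outer
  flanker, and it is fitted on outward-realigned errors so that positive
  `mu` means outward. A global shift of all components is a plausible
  alternative; the target-only form was chosen because the bias hypothesis
  concerns the target's perceived orientation, not the flankers'.
* **Continuous degrees.** Stimulus orientations are drawn from the 180
  discrete values actually displayed, but the likelihood treats
  orientations as continuous — the response wheel is continuous and the
  uniform term is exact either way.

## Fitting

`fit_mle()` maximises the likelihood of one observer-condition's trials by
multi-start bounded optimisation:

* the mixture weights `(P_T, gamma, beta_1..k)` are reparameterised through
  an exact softmax, so the simplex constraint `gamma + sum(beta) <= 1`
  holds by construction, never by penalty;
* `sigma` is optimised as a bounded transform of the von Mises
  concentration `kappa` (defaults `sigma` in `[0.5, 80]` degrees), and `mu`
  through a bounded logistic transform (default `[-45, 45]` degrees);
* starting points come from a Latin hypercube (`n_starts = 20` by default),
  with the weight coordinates mapped to a flat Dirichlet draw on the
  simplex; each start is refined by Nelder–Mead (relative tolerance 1e-8)
  with a BFGS polish, and the best optimum is kept;
* everything is deterministic given `(errors, seed)`; the caller's RNG
  state is left untouched.

With at most 7 free parameters and smooth, unimodal-in-practice likelihood
surfaces, 20 Latin-hypercube starts are generous; the test suite checks
that independent seeds land on the same optimum to 1e-4 in log-likelihood.
Degenerate inputs are handled explicitly: fewer than 20 trials is an error,
a model incompatible with the trial's flanker count is an error, and a fit
whose starts all fail returns a flagged `converged = FALSE` result rather
than crashing a batch.

Models are compared per observer with `aicc()`
(`-2 logLik + 2k + 2k(k+1)/(n-k-1)`); `compare_models()` breaks exact ties
by smaller `k`, then catalog order. At the group level
`fit_condition_set()` averages AICc across observers per model and reports
each model's difference from the condition's best mean — the quantity
usually plotted in model-comparison figures.

### Candidate sets

Following the comparison logic of the experiments this package targets,
uncrowded data are fitted with S only; two-flanker data with
{S, M, 2M, 2B}; four-flanker data with {S, M, 4M, 4B}. Bias models are
fitted on outward-realigned errors; the symmetric models are fitted on raw
errors (their likelihood is invariant under realignment, which the tests
verify). In the second experiment's two-flanker condition both flankers are
inner, so outward realignment is undefined; bias models are dropped there
with a message. Candidate sets are a configurable argument.

## The synthetic generator

`generate_design()` reproduces the two radial designs:

| | target | two-flanker | four-flanker |
|---|---|---|---|
| Experiment 1 | 7.0° | 1I 5.5°, 1O 8.5° | 2I 4°, 1I 5.5°, 1O 8.5°, 2O 10° |
| Experiment 2 | 8.5° | 2I 5.5°, 1I 7° | 3I 4°, 2I 5.5°, 1I 7°, 1O 10° |

(eccentricities in degrees of visual angle; adjacent items 1.5° apart).
Defaults are 200 trials per condition per observer — 600 in total over the
three crowding conditions — with target and flanker orientations drawn
uniformly from the 180 discrete orientation values and every flanker
constrained by rejection sampling to differ from the target by at least 15°
on the circle (per-draw acceptance probability 151/180, so the sampler
terminates quickly). Hemifield is balanced within each observer-condition
cell and carried as metadata only; eccentricities never enter the
likelihood. Block structure is not modelled beyond total counts, since no
implemented analysis depends on it. No flanker–flanker separation is
imposed — only the target-relative restriction is part of the design.

`simulate_responses()` inverts the mixture generatively: per trial a latent
source (target / guess / flanker *i*) is drawn with probabilities
`(P_T, gamma, beta_i)`, and the response is the source orientation plus von
Mises noise (guesses are uniform on the wheel). The latent source is
recorded so tests can check, e.g., that flanker-latent trials really do
cluster around that flanker. Von Mises noise is sampled with the
Best–Fisher envelope-rejection algorithm implemented in `rvm_deg()`.

What the generator deliberately does **not** emulate: sequential effects,
lapses correlated over time, observer-specific parameter heterogeneity
beyond what a scenario specifies, eye movements, and stimulus rendering.
Passing recovery tests on this generator therefore shows that the
estimation machinery is correct and well-calibrated at the study's design
and sample sizes — not that the mixture model is the true model of any
particular observer.

## Derived summaries

* `precision_summary()`: per observer-condition, the inverse of the
  variance of the errors in radians (default), or the inverse SD via
  `mode = "sd"` — both conventions circulate for this summary, sometimes
  within a single report, so the switch is explicit and the default is the
  variance form. Group averages should be means of per-observer precisions,
  not pooled-trial estimates. Zero-variance cells yield a flagged infinite
  precision.
* `realign_outward()`: flips each trial's error and offsets so the
  first-outer flanker is on the positive side; a positive mean realigned
  error is an outward bias. Idempotent.
* `flanker_report_rates()`: per-flanker fitted weights from the
  independent-misreport fits, with `P_T` and the guess rate as their own
  rows, plus group means/SDs. The observer summary table also takes its
  parameter columns from the condition's maximal independent model
  (S / 2M / 4M) so that per-flanker rates are always available, while
  `best_model` reports the per-observer AICc winner over the full
  candidate set.
* `flanker_relative_histogram()`: binned distribution of reports around
  each flanker's value (default 10-degree bins), for plotting and eyeball
  checks.

`circ_moments()` exposes both linear and circular moments of error sets;
for error distributions concentrated well inside `(-90, 90]` the two
coincide to rounding, and the precision summary uses the linear variance.

## Validation by simulation

The test suite validates the whole chain at the study's own scale:

* densities integrate to 1 for all six models across random parameters;
* the pooled/equal-split nesting identity holds to 1e-9;
* fitting a 10,000-trial two-flanker set generated at
  `gamma = 0.05, sigma = 15, beta_1I = 0.05, beta_1O = 0.25` recovers each
  weight within ±0.03 and `sigma` within ±1.5°; at 200 trials the mean
  absolute weight error over 100 replicates stays at or below 0.05;
* with 13 simulated observers × 200 trials, the generating two-misreport
  model wins the group mean-AICc comparison against S and M in at least
  80% of 20 replicated experiments, while data generated from S never hand
  2M a spurious advantage above 2 AICc points;
* generating the four-flanker condition with weights
  `(0.07, 0.07, 0.24, 0.07)` for (2I, 1I, 1O, 2O) — the reported group
  means of the asymmetry this family of models was built to capture — and
  fitting 4M reproduces the adjacent-outer dominance (`beta_1O` above the
  mean of the other three) in at least 90% of replicates.

Replicate counts (20, 10, 100) and `n_starts` were chosen once as the
smallest sizes at which these stochastic checks are stable; the thresholds
themselves are the published tolerances of the checks, not tuned values.

## Known limitations

* Point estimates only: no standard errors, no Bayesian posterior, no
  hierarchical pooling across observers — each observer-condition is fitted
  independently.
* The bias models' target-only parameterisation is one of several
  defensible readings of "mixture with mean bias"; conclusions about small
  `mu` values should not lean on this choice.
* Group-level inferential statistics (ANOVAs, t-tests, effect sizes) are
  out of scope; the pipeline emits the per-observer tables those tests
  consume.
* Weighted-averaging (feature-pooling) models are not implemented; the
  bias variants are the only averaging-like mechanism included.
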