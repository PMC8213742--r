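---
title: "Methods: the relative-starting-time DDM and the synthetic cued-attribute study"
author: "rstddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the relative-starting-time DDM and the synthetic cued-attribute study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rstddm` implements a two-boundary diffusion decision model for binary food
choices in which the two choice attributes — the taste and healthiness of the
options — can begin to influence the decision at different moments. Evidence
$x(t)$ starts at $x_0 = 2\,\mathrm{sp} - 1$ between fixed absorbing thresholds
$[-1, +1]$ (upper = choose the left option) and evolves as

$$dx = v(t)\,dt + \sigma\,dW,$$

with a piecewise-constant drift

$$v(t) = \beta
       + \omega_\text{taste}\,\mathrm{td}_{LR}\,\mathbf{1}[t \ge s_\text{taste}]
       + \omega_\text{health}\,\mathrm{hd}_{LR}\,\mathbf{1}[t \ge s_\text{health}],$$

where $\mathrm{td}_{LR}$ and $\mathrm{hd}_{LR}$ are the left-minus-right
rating differences, $\beta$ is a constant drift intercept, and the *relative
start time* is $RST = s_\text{health} - s_\text{taste}$ (positive: taste is
considered first). The observed response time is the first-passage time plus
a non-decision time (NDT). Because the thresholds are fixed, the diffusion
noise $\sigma$ is a free parameter and sets the scale; seven parameters are
free in total ($\sigma$, sp, NDT, RST, $\omega_\text{taste}$,
$\omega_\text{health}$, $\beta$).

Two modelling conventions were genuinely open and are resolved as follows:

* **Onset anchoring.** Attribute onsets are measured within decision time,
  i.e. after the NDT: the earlier attribute starts at $t = 0$ and the later
  one at $t = |RST|$. Since the NDT is a separate parameter, anchoring the
  onsets to the accumulation clock keeps the two mechanisms distinct.
* **Attribute inputs.** Raw session-1 rating differences are used (not
  z-scored) for the diffusion model and for the choice regression; the
  response-time regression z-scores them. This mirrors how the original
  analyses specify each model. A z-scoring flag exists for the choice
  regression (`fit_choice_model(z_score = TRUE)`).

## Numerics

**Simulation** (`simulate_trials`) uses an Euler scheme whose Gaussian
transition is *exact* under piecewise-constant drift (steps are aligned to
the attribute-onset switch), plus a Brownian-bridge correction for
within-step boundary crossings. This removes the leading-order
discretisation bias in choice probabilities: at the default `dt = 0.002` s,
simulated choice probabilities are indistinguishable from the constant-drift
closed form at $n = 10^5$ (3 Monte-Carlo SEs), which a naive
Euler-with-thresholding scheme fails by an order of magnitude.

**First-passage densities** (`fpt_density`) are computed by Crank–Nicolson
finite differences on the forward Kolmogorov equation with absorbing bounds
(defaults `dx = 0.02`, `dt = 0.005` s). Two details matter: a Rannacher
(backward-Euler) start damps the oscillations that the delta initial
condition would otherwise produce, and the same damping is re-applied around
the drift switch at $|RST|$ where the solution has a kink. Per time step the
absorbed mass is the exact discrete mass balance, allocated to the two
boundaries in proportion to the one-sided diffusive boundary fluxes, so
"absorbed + surviving = 1" holds to round-off *by construction*
(`conservation_tol` in the run configuration documents the numerical slack,
1e-4); the accuracy of the time course and the upper/lower split is tested
against $10^6$-trial simulations (sup-norm tolerance 0.05 on bin-averaged
densities, about 2–3% of the peak density).

**Likelihood** (`rst_loglik`) evaluates the density at (chosen boundary,
$rt - \mathrm{NDT}$), flooring each trial's density at $10^{-10}$ so stray
RTs cannot produce $-\infty$. Censored (no-response) trials are excluded by
default; `censoring = "truncate"` instead renormalises by the probability of
responding before the deadline. The original analysis did not state which
convention it used; exclusion is the default because censoring is rare
(about 1% of trials at the generative parameters).

**Fitting** (`fit_subject`) maximizes the likelihood over transformed
parameters: $\log\sigma$, $\mathrm{logit}(\mathrm{sp})$, NDT mapped by a
scaled logistic to $(0, \min rt)$, and unbounded RST/weights/bias —
multi-start Nelder-Mead with seeded jitter. Standard errors are
curvature-based (numerical Hessian, delta method). `fit_hierarchical` pools
subjects: the default *two-stage* mode summarizes subject MLEs by cohort
moments; the *mcmc* mode is a Metropolis-within-Gibbs sampler with normal
group priors over the transformed parameters (conjugate updates for the
group mean and variance; weakly-informative hyperpriors, prior sd 5 on
transformed group means, inverse-gamma(2, 0.1) on group variances). The two
modes agree within 0.1 a.u. on group means in the test suite. Convergence
policy (flagged, not silent): split-$\hat R$ < 1.01 and crude ESS ≥ 400.

## The synthetic study

The generator emulates the study conditions: 23 subjects, five sessions over
two weeks; taste and health ratings on a continuous $-5..+5$ scale (all 180
items in sessions 1 and 5, a fixed 60-item subset chosen to span the taste
range in sessions 2–4); 210 choice trials per session in 9 health-cued and
8 natural-cued blocks (health-cued totals drawn around $110.6 \pm 5.2$ and
forced to a 210 total); a 3-s choice deadline; and pair lists fixed by each
subject's session-1 ratings and reused across sessions.

Choices it does *not* emulate: real food images, day-of-week or hunger
effects, sequential dependencies between trials, and rating drift with a
structured (non-exchangeable) covariance. Passing tests therefore show that
the estimators and reliability statistics behave correctly under the study's
design and noise model, not that they are robust to every failure mode of
real raters.

Deliberate generator choices:

* **Item latents** are bivariate normal (sd 2.2, taste–health correlation
  $-0.3$, clipped to the scale). The mild negative correlation makes
  taste/health conflicts common, which the challenge-pair constraint
  requires; snack-food sets look like this in practice.
* **"Healthier item"** of a pair is the one with the higher session-1 health
  rating by that subject; exact ties are never paired (the original design
  is silent on ties, and excluding them keeps $hd > 0$ strictly).
* **Challenge pairs** are pairs whose tastier-rated item is strictly less
  healthy. The original description adds "similar ratings" without a
  threshold, so the generator exposes `challenge_td_max` (default `Inf`)
  rather than guessing a value; half the pairs are challenge pairs by
  default.
* **Rating noise** is latent + subject-by-item offset (sd `between_sd` = 1)
  + session noise (`within_sd`, default taste 2.0 / health 1.2). The implied
  test-retest ICC is $(\mathrm{var}_{latent} + \mathrm{between}^2) /
  (\mathrm{var}_{latent} + \mathrm{between}^2 + \mathrm{within}^2)$, so the
  defaults place health ratings in the excellent range and taste ratings in
  the fair range, matching the qualitative contrast reported for real
  raters.
* **Between-subject parameter spread.** The published group table reports
  "mean ± SE", but the same report's group-mean HDIs are an order of
  magnitude narrower than those ± values, and reading them as SEs of the
  mean would imply between-subject spreads (± values × √23) that put a
  sizeable fraction of subjects at negative diffusion noise. The ± values
  are therefore used directly as the between-subject sd when drawing
  cohorts — the reading consistent with both the HDI widths and a physically
  admissible cohort.
* **Stratified cohort draws.** `draw_subject_params(stratified = TRUE)`
  draws subject deviations as randomly permuted normal quantiles, so the
  realized cohort mean equals the generative group mean. Recovery analyses
  then measure estimator error rather than finite-cohort sampling noise.
  Set `stratified = FALSE` for fully random cohorts (used in
  `recovery_study` coverage checks).

## Reliability statistics

`icc_a1` is the two-way random-effects, absolute-agreement, single-measure
intraclass correlation computed from the ANOVA mean squares, with the F test
against ICC = 0 on a Satterthwaite (fractional) denominator df and the
standard F-quantile confidence interval. It is validated against a
brute-force `aov()`-based oracle to 1e-12 rather than against any named
package. Interpretation bins are left-closed at the conventional cut points:
Poor < 0.40 ≤ Fair < 0.60 ≤ Good < 0.75 ≤ Excellent. Zero-variance matrices
return a flagged degenerate result. Missing cells are handled by listwise
deletion with a logged count (the emulated design has complete data). For
per-subject rating reliability, items are rows and sessions are columns
(configurable via `unit = "item"` for the per-item analysis).

## Known limitations

* RST is weakly identified whenever $\min(|\omega_\text{taste}|,
  |\omega_\text{health}|) \approx 0$: a near-zero weight and a long onset
  delay are nearly observationally equivalent. The package warns when a
  group-level weight interval covers zero and an RST estimate is reported,
  and the acceptance suite reproduces the degradation of RST recovery and
  reliability in the weak-weight (natural-cued-like) regime. Fit the
  `model = "standard"` variant (RST fixed at 0) in that regime.
* The regressions use `lme4` (Wald 95% intervals) with a reduced default
  random-effect structure `(1 + hd + td + condition | subject)`; the full
  subject-level mirror of all population terms is available via
  `random = "full"` but is slow and frequently singular at desk scale.
* Two-stage group summaries ignore subject-level estimation uncertainty
  (no shrinkage); at ~100 trials/subject and 20 subjects this changes group
  means by less than the Monte-Carlo error, which is why it is the default
  desk-scale mode.

## Problem sizes used in the checks

The test suite and the acceptance script run at desk scale by choice:
recovery cohorts of 10–20 subjects with one 210-trial session each
(~100 trials per condition fit), $10^5$-trial simulator-vs-closed-form
checks, $10^6$-trial solver-vs-simulation checks, and 100-matrix ICC
oracle/coverage sweeps. The full five-session, 23-subject pipeline is run
end-to-end at reduced trial counts in the pipeline tests and at full scale
via `run_synthetic_study(run_config())`.
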