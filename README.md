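# rstddm

Simulation, likelihood, and hierarchical estimation of the
**relative-starting-time diffusion decision model (rstDDM)** for two-attribute
food choices, together with the full analysis pipeline of a five-session
*cued-attribute food choice* study: hierarchical choice and response-time
regressions, prediction-from-ratings accuracy, and test-retest reliability via
the two-way agreement intraclass correlation ICC(A,1).

## The scientific problem

In the cued-attribute food choice task, participants choose between two food
items under two cue conditions: *natural* (choose freely) and *health-cued*
(consider healthiness before choosing). The task is used to study dietary
self-control and to evaluate interventions, which only makes sense if its
individual-level measures are stable across repeated administrations. This
package provides the measurement machinery for that question: a process model
of the decisions, the regression analyses of choices and response times, and
reliability statistics — all runnable end-to-end on a seeded synthetic study
with known ground truth (23 subjects, 5 sessions, ratings of 180 foods on a
−5..+5 scale, 210 choice trials/session in 9 health-cued + 8 natural-cued
blocks, 3-s deadline).

## The model

Evidence `x(t)` diffuses between fixed absorbing bounds `[-1, +1]`
(upper = left option) from a start point `2·sp − 1`:

    dx = v(t)·dt + σ·dW
    v(t) = β + ω_taste·td_LR·1[t ≥ s_taste] + ω_health·hd_LR·1[t ≥ s_health]

`td_LR`/`hd_LR` are left-minus-right taste/health rating differences, and
`RST = s_health − s_taste` is the *relative start time*: positive RST means
taste enters the drift before healthiness. Response time = first-passage time
+ non-decision time (NDT). Seven free parameters: noise σ, start-point bias
sp, NDT, RST, ω_taste, ω_health, drift bias β. First-passage densities come
from a Crank–Nicolson solution of the forward Kolmogorov equation; the
simulator uses exact Gaussian steps with a Brownian-bridge boundary-crossing
correction.

## Worked example

Simulate one subject's session at health-cued generative parameters, fit the
model, and inspect the recovery:

```r
library(rstddm)

p <- rst_params(noise = 0.98, sp_bias = 0.49, ndt = 0.59, rst = -0.03,
                w_taste = 0.32, w_health = 0.9, drift_bias = 0.05)

set.seed(1)
td <- rnorm(300, 0, 3); hd <- rnorm(300, 0, 3)   # rating differences
sim <- simulate_trials(p, td, hd)                 # 3-s deadline by default
trials <- data.frame(td_lr = td, hd_lr = hd, chose_left = sim$chose_left,
                     rt = sim$rt, censored = sim$censored)
fit_subject(trials, control = fit_control(seed = 1))
```

```
rst-DDM fit: 294 trials, logLik = -47.33, convergence = 1
           estimate     se
noise        1.0143 0.0545
sp_bias      0.4877 0.0190
ndt          0.5935 0.0151
rst         -0.0011 0.0126
w_taste      0.2895 0.0324
w_health     0.8888 0.0626
drift_bias   0.1204 0.1092
```

Six of the 300 trials hit the 3-s deadline and are excluded as censored. The
true weights (0.32 taste, 0.90 health), NDT (0.59 s) and noise (0.98) are
recovered within about two standard errors; the small generative RST
(−0.03 s) is statistically indistinguishable from zero at this sample size,
which is exactly the identifiability behaviour the model documentation
describes.

The whole synthetic study — ratings, designs, five sessions of choices,
per-session×condition fits, regressions, and reliability tables — runs from
one seeded configuration:

```r
run_synthetic_study(run_config(seed = 1), outdir = "run1")
```

which writes `trials.tsv`, `ratings.tsv`, `truth.json`, `fits.tsv`,
`regressions.tsv`, `reliability.tsv`, `report.md`, and `run.log` (identical
seed → byte-identical tables). A thin CLI with subcommands
(`simulate|fit|regress|reliability|report|all`) is in
`inst/scripts/rstddm_pipeline.R`.

Reliability example — ICC(A,1) on a subjects × sessions matrix:

```r
set.seed(2)
m <- matrix(rnorm(23 * 5), 23, 5) + rnorm(23, sd = 2)  # stable subjects
icc_a1(m)
```

```
ICC(A,1) = 0.781 (Excellent), F(22, 90.4) = 18.32, p = 2.08e-24, 95% CI [0.649, 0.885]
```

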