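---
title: "Models and methods behind dynaprl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dynaprl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dynaprl` studies how agents weight wins and losses differently while
learning in a volatile two-armed bandit. This vignette documents the task
environment, the four reinforcement-learning models, the fitting and
hierarchical-inference machinery, the model-independent behavioral
analyses, and the numerical and design choices behind them — including
what the synthetic cohorts do and do not emulate about real behavioral
data.

## The task environment

The dynamic probabilistic reversal learning (dynaPRL) environment is a
two-lever bandit (actions `A1` = left, `A2` = right) organized in blocks
of three types, distinguished by the contrast between the two levers'
reward probabilities:

| block | better action | worse action |
|-------|---------------|--------------|
| HC (high contrast)  | 0.80 | 0.10 |
| LC (low contrast)   | 0.60 | 0.30 |
| NC (no contrast)    | 0.45 | 0.45 |

Blocks switch every 15–30 trials (scheduled length drawn uniformly), with
two constraints: a no-contrast block never follows another, and the
better side never repeats across consecutive contrast blocks. A due
transition in a contrast block is *deferred* while the last four choices
were all incorrect. We read the consecutive-error rule as deferral —
switching contingencies mid-failure would make them unlearnable, and
deferral preserves the 15–30 schedule as a minimum; `task_config()`
exposes `error_rule` so the rule can be disabled. The low-contrast worse
probability is 0.30 by default (the steeper 0.60/0.10 variant is a
configuration away), matching the block-contrast ordering HC > LC > NC.

On rewarded HC/LC trials after the 12th trial of a block, 40% of rewards
are halved (16 µL) or doubled (66 µL) with equal odds instead of the
standard ~33 µL. The manipulation affects the recorded volume only: all
learning models consume the binary outcome, since every update rule is
written in terms of the reward indicator.

A simpler single-reversal training environment (`run_prl_session()`,
0.70/0.10) reverses once an exponential moving average of correctness
(8-trial convention, smoothing 2/(8+1)) exceeds 0.75 — thereafter with
probability 0.10 per trial, forced after 20 eligible trials.

Response timing is not simulated; omitted responses ("invalid" trials)
are instead injected by the cohort generator at a configurable rate
(default 0.5%, i.e. below the reported sub-1% rate) and excluded from
every downstream computation.

## The four learning models

All models choose by softmax, `p(a) ∝ exp(β V_a)`, share binary rewards
`R ∈ {0,1}`, start each session at `V = (0, 0)` (session-level fitting
implies session-level reset; values carry across block transitions within
a session), and are available both in likelihood mode (`session_nll()`)
and generative mode (`simulate_agent()`), computed by one shared filter
so the two modes cannot drift apart.

* **standard** — delta rule. `RPE = R − V(c)`; `V(c) += α·RPE`.
  Parameters `α ∈ (0,1)`, `β ∈ [0,20]`.
* **avgrpe** — averaged-RPE model. A running trace
  `avgRPE ← α·RPE + hW·avgRPE` updates the chosen value by the trace
  itself (`V(c) += avgRPE`). `hW ∈ [0, 0.75]`. At `hW = 0` it reduces
  exactly to the standard model; `α` deliberately plays a dual role
  (scaling the RPE inside the trace), which is the literal reading of
  the update. The absolute value `|avgRPE|` serves as a trial-by-trial
  uncertainty proxy.
* **grs** — global-reward-state model. A reward trace
  `Rtrace ← Rtrace + (R_prev − Rtrace)·αR` (an EMA of past outcomes,
  updated from the previous trial's outcome; the first trial of a session
  leaves the initial value 0 untouched) enters the prediction error,
  `RPE = R + wR·Rtrace − V(c)`; `V(c) += α·RPE`. `αR ∈ [0,1]`,
  `wR ∈ [−1,1]`; at `wR = 0` it reduces to standard. With binary rewards
  the trace is confined to [0,1].
* **asym5** — five-parameter asymmetric model. After wins the chosen
  value moves by `α⁺·(R − V)` and the unchosen value is multiplied by
  `γ⁺`; after losses `α⁻` and `γ⁻` apply. Decay rates are reported as
  `1 − γ`. At `α⁺ = α⁻` and `γ⁺ = γ⁻ = 1` it reduces to standard.

Numerical choices: the softmax subtracts the max before exponentiating;
choice probabilities are floored at 1e-9 inside the log; β is capped at
20 (beyond which choices are effectively deterministic and the
likelihood flat).

## Maximum-likelihood fitting and model comparison

`fit_session()` minimizes the session's negative log-likelihood with
L-BFGS-B under box bounds, from 10 restarts. Starting points are drawn
uniformly within the bounds, then *pre-screened*: 50 candidates are
evaluated once and the 10 best launch optimizations. The pre-screen
matters because the likelihood has a flat plateau at `α → 0` (values
never move, so β is unidentified); quasi-Newton runs started at high β
reliably fall onto it, and without screening a meaningful fraction of
low-β sessions lose all 10 restarts to the plateau. Model comparison uses
`BIC = 2·nLL + k·ln(n)` per session; subjects are summarized by mean BIC
(summed BIC is also reported), and ties go to the model with fewer
parameters.

Two recovery experiments validate the machinery end to end.
`parameter_recovery()` refits 100 simulated sessions of 400 trials with
parameters drawn from plausible behavioral ranges (α ∈ [0.1, 0.8],
β ∈ [1, 8]); true-versus-recovered correlations are ~0.93 (α) and ~0.95
(β). `model_recovery()` builds the 4×4 generator-by-winner confusion
matrix from 25 subjects per generator (2 sessions × 500 trials). The
generative regimes (`recovery_regimes()`) are chosen so that each model's
distinctive mechanism is expressed, because a confusion analysis is only
informative where the models are distinguishable in principle. The GRS
regime deserves a note: with a *positive* trace weight the model is
nearly behaviorally equivalent to standard RL — the trace inflates both
actions' learning targets roughly equally, which to first order rescales
the softmax temperature, and the likelihood advantage (~0.005–0.01 nats
per trial) stays below the BIC penalty at session scale. The regime
therefore uses a fast, strong, negative-weight trace (αR = 0.5,
wR = −0.9), where reward history sharpens the value contrast and the
mechanism is identifiable (~0.035 nats/trial).

## Hierarchical two-group inference

The asymmetric model's five parameters are compared between two groups
with a hierarchical model: on an unconstrained scale, subject `j`'s
parameter `p` is drawn from `Normal(μ_p + s_j δ_p / 2, σ_p)` with
`s_j = ±1` by group, mapped to the bounds by a logistic transform
(β scaled to (0, 20]). Priors are weakly informative:
`μ ~ N(0,1)`, `δ ~ N(0,0.5)`, `σ ~ half-N(0.5)`. The group contrast is
summarized by the directed Bayes factor, the ratio of posterior mass of
`δ` above versus below zero (capped at the draw count when one side is
empty), along with 80%/95% highest-density intervals.

Sampling uses a purpose-built adaptive Metropolis-within-Gibbs sampler
(in C++): `(μ_p, δ_p)` have a conjugate bivariate-normal Gibbs update;
`log σ_p` and every subject-level parameter take adaptive random-walk
steps tuned toward 44% acceptance during warmup only (so post-warmup
draws form a time-homogeneous chain). Defaults are 2 chains × 1,000
draws after 500 warmup iterations; split-R̂ per parameter is reported
and the fit is flagged when any exceeds 1.05. Chains are seeded
independently, making results exactly reproducible.

Validation: with an injected `α⁺` group difference of 0.15 (8 subjects
per group, 5 sessions × 300 trials), the δ posterior shifts positive
with dBF > 3 in 10/10 seeded replications. Posterior subject-level means
correlate with per-subject MLE fits (r > 0.6), the expected shrinkage
behavior.

A calibration caveat worth stating plainly: under a true null, the dBF
falls in [1/3, 3] exactly when the posterior mass of δ above zero lies
in [0.25, 0.75]. For a well-calibrated posterior the standardized group
difference behaves like a standard normal under the null, which puts
that probability near 50%, rising only as far as the δ prior shrinks the
posterior toward zero. At desk scale (5+5 subjects, 2 × 150 trials) we
measure 60–70% of null replications inside [1/3, 3] — the value the
shrinkage arithmetic predicts. A substantially higher null "calibration"
rate would require a prior that dominates the data; we prefer the
honest posterior and recommend interpreting dBFs near 3 accordingly.

## Model-independent behavioral analyses

A trial is a *win-stay* if rewarded and the next valid same-session
choice repeats it, a *lose-shift* if unrewarded and the next choice
differs. Probabilities are micro-averages: event counts pooled across
sessions first, then divided by pooled win/loss counts. Strata combine
phase (early = first 6 block trials, late = 7th onward, taken from the
outcome trial), block type, and action class (better/worse; undefined in
NC blocks). Stay/shift pairs may span a block transition but never a
session boundary. Action-difference scores subtract worse-action from
better-action probabilities. The perseveration curve tracks, around each
block transition, the probability of choosing the *previous* block's
better action (5 trials pre, 12 post; for transitions out of NC blocks
one action is designated "correct" at random).

## Trial-by-trial latent-state analyses

Three analyses link fitted latent quantities to stay/shift behavior, all
using binomial logistic regression on z-scored predictors (the outcomes
are binary, so regression slopes play the role of correlations):

* **k-sweep** — a weighted RPE `wRPE_t = k·RPE_t + (1−k)·RPE_{t−1}`
  (standard-model RPEs; the first trial of a session uses 0 for the
  missing previous RPE) is built for each `k` on [0.5, 1] in steps of
  0.025, and the stay (win trials) or shift (loss trials) indicator is
  regressed on it; the best `k` maximizes the absolute slope. A
  constructed dependency with `k = 0.8` over 10,000 trials is recovered
  within one grid step.
* **latent-choice correlation** — win-stay (or lose-shift) regressed on
  `|avgRPE|` (avgRPE-model fit) or the reward trace (GRS-model fit),
  restricted by default to better actions in the late phase, per block
  type. Degenerate strata (constant predictor, single-valued outcome, or
  fewer than 30 events) are reported as missing, never dropped silently.
* **median-split interaction** — better-action late-phase win trials are
  split at the within-set medians of the reward trace and `|avgRPE|`
  into four cells; win-stay probability is reported per cell. Ties at
  the median go to the "low" cell, deterministically.

z-scores are computed within the analyzed stratum. Latent traces come
from per-session fits (`latent_traces()`), mirroring session-level
estimation.

## Synthetic cohorts: what they emulate, and what they do not

`generate_cohort()` samples per-subject parameters from two group
distributions (`Normal(mean ± delta/2, sd)`, truncated to bounds) and
simulates every session in the dynaPRL environment. The default spec
emulates the structure of a 9 + 5 two-group rodent cohort under the
asymmetric model, with group A learning faster from wins
(Δα⁺ = 0.15), slightly faster from losses (Δα⁻ = 0.05) and decaying
unchosen values more after losses (Δγ⁻ = −0.20) — the loss-decay
contrast deliberately dominates the loss-learning-rate contrast, which
is what makes group A simultaneously win-stay more and lose-shift less;
equal-magnitude contrasts cancel in the lose-shift direction. Defaults
use 5 sessions × 300 trials per subject (scaled-down exposure relative
to a multi-week experiment, keeping test runtimes in minutes).

What passing tests on these cohorts do *not* show: synthetic agents obey
the fitted model family exactly, have stationary parameters, no
within-session drift in motivation or satiety, no response-time
structure, and omissions occur completely at random. Real behavioral
data violate all of these, so recovery results here bound what the
machinery can do under ideal conditions — they do not certify parameter
estimates on any particular real dataset, and the package makes no
attempt to reproduce any published cohort's numerical values.

## Known limitations

* The dBF null-calibration rate is a property of posterior-odds
  statistics, not a tunable of this implementation (discussed above).
* The hierarchical sampler is specific to the five-parameter model; the
  three session-level models are compared by BIC only.
* Reward magnitude is metadata; magnitude-sensitive utilities are out of
  scope, as are perseveration kernels and counterfactual updating.
* The mixed-effects significance layer often applied to stay/shift
  summaries is intentionally absent; the package produces the summary
  tables.
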