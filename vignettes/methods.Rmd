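---
title: "Modelling social learning from volatile advice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social learning from volatile advice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(advicehgf)
```

# The paradigm and its generative structure

`advicehgf` models a two-player economic game. On each trial a *player*
predicts a binary lottery outcome given a pie-chart cue showing the true
outcome probability (six balanced cue types: 75:25 down to 25:75) and the
recommendation of an *adviser* whose private information predicts the
outcome at a constant 80%. The player's score rises by 1 with each
correct prediction and falls by 1 with each incorrect or missed one. The
adviser's own bonuses depend on the *player's* final score landing in the
adviser's gold (35–50) or silver (95–110) range, which lie below the
player's own silver (>65) and gold (>115) targets — so the adviser's
incentive to help or mislead changes as the game progresses. A control
variant removes intentionality: a blindfolded adviser draws cards from
six decks whose predictive accuracy is 80% or 20%.

The player's computational problem is therefore twofold: estimate the
current reliability of the advice, and estimate how quickly the adviser's
intentions are drifting — the *volatility* of the social context.

## The synthetic-data generator

The study's behavioural data were never deposited, so the package
generates the design from scratch ([`make_task_schedule()`],
[`simulate_adviser()`], [`simulate_player()`], [`simulate_cohort()`]).
The generator reproduces the printed design constants: 192 prediction
trials plus 8 rating probes, balanced cue types, 80% adviser information
accuracy, and 80%/20% control decks. Where the design leaves details
open, the package fixes them once:

* **Adviser strategies.** Three kinds, mirroring the debriefing reports:
  `helpful` advisers always pass on their private information;
  `uninformative` advisers match the outcome at chance;
  `incentive_switching` advisers pass on their private information except
  while the player's score sits inside the gold or silver range, where
  they advise the opposite colour (with configurable probability,
  default 1 — whether real advisers misled deterministically inside their
  ranges is not documented, so the probability is exposed as a
  parameter). A 16-subject cohort with 4 helpful, 3 uninformative and 9
  switching advisers mirrors the observed breakdown.
* **Control deck switching** is not specified; the blindfolded adviser
  switches to a different random deck in blocks of 20–40 trials (drawn
  uniformly, seeded), with 3 high- and 3 low-accuracy decks.
* **Rating probes** were "presented at the same times across subjects";
  probe positions are drawn once per cohort seed and shared. Probe
  trials carry no prediction, no score change, and no belief update.
* **Missed responses** are never generated, but the data reader accepts
  missing responses and the likelihood skips those trials: the score
  penalizes misses, the models only explain observed choices.
* **Simulated ratings** are the agent's current reliability estimate
  s(μ̂₂) discretized to {0, 0.5, 1} by thirds (optionally with Gaussian
  noise before discretizing). The study did not model ratings
  generatively; this choice makes the rating-validation analysis a clean
  positive control.

What the generator does *not* emulate: reaction times, payment logistics
beyond the score, and human departures from the model class (e.g.
sequential choice biases). Passing recovery tests therefore demonstrate
internal consistency of the pipeline on data generated *by these models
under this design*, not that human data would identify the same models.

# Perceptual models

Three belief-updating filters run over the binary advice accuracies
u⁽ᵏ⁾ ([`filter_sequence()`]):

**Three-level HGF.** Hidden states are the advice accuracy x₁ ∈ {0,1}
with P(x₁ = 1) = σ(x₂); the adviser's tendency x₂, a Gaussian random
walk whose step variance is exp(κx₃ + ω); and the log-volatility x₃, a
Gaussian random walk with step variance ϑ. The variational update per
trial is, at level 2,

μ̂₁ = σ(μ₂),  v̂₂ = exp(κμ₃ + ω),  π̂₂ = 1/(σ₂ + v̂₂),
δ₁ = u − μ̂₁,  π₂′ = π̂₂ + μ̂₁(1 − μ̂₁),  μ₂′ = μ₂ + δ₁/π₂′,

and at level 3, with w₂ = v̂₂/(σ₂ + v̂₂) and the volatility prediction
error δ₂ = (σ₂′ + (μ₂′ − μ₂)²)/(σ₂ + v̂₂) − 1,

π̂₃ = 1/(σ₃ + ϑ),  π₃′ = π̂₃ + (κ²/2)·w₂·(w₂ + (2w₂ − 1)δ₂),
μ₃′ = μ₃ + (κ/2)·(w₂/π₃′)·δ₂.

Updates are precision-weighted prediction errors: the learning rate is
large when the input is informative or the current belief uncertain.
π₃′ can turn non-positive for extreme parameter settings (large ω or κ
with strong surprise); this is the model's own pathology, and the step
raises a rejection condition that the fitter maps to log-joint = −∞,
vetoing the parameter vector. Forward simulation never hides it.

**Reduced (no-volatility) HGF.** Identical level-1/2 computation with
level 3 frozen at its initial value: an agent that ignores the
possibility of changing intentions. Nesting holds exactly: as κ → 0 the
full filter's level-1/2 quantities coincide with the reduced filter's.

**Rescorla–Wagner.** v′ = v + α(u − v) with constant learning rate α.

Two diagnostics summarize the HGF's adaptive learning
([`learning_rates()`]): the effective first-level rate
lr₁ = (μ₁ − μ̂₁)/δ₁ (the realized update of the predicted reliability per
unit prediction error — defined operationally because it is exactly
testable), and the third-level rate lr₃ = (κ/2)·w₂/π₃, the coefficient
on δ₂ in the μ₃ update.

An independent check accompanies the filter: an exact sequential
Bayesian filter on a discretized (x₂, x₃) grid implementing the
generative model directly (tests, `grid_filter_oracle`). On a 240-trial
helpful-then-misleading schedule at prior-mean parameters the two
trajectories of predicted advice accuracy correlate above 0.9.

# Response models

The response model maps beliefs to the probability of *following* the
advice ([`response_loglik()`]). The predicted advice reliability is
m⁽ᵏ⁾ = σ(μ̂₂⁽ᵏ⁾) for the HGF variants (the pre-update prediction, so the
mapping is causal) and the pre-update value v⁽ᵏ⁻¹⁾ for RW. With the
pie-chart probability of the advised colour c⁽ᵏ⁾ and advice weight ζ,
the integrated belief is b = ζm + (1 − ζ)c. Choice probabilities follow
the exponentiated Luce rule p = b^β/(b^β + (1 − b)^β) — the standard
sigmoid mapping the unit interval onto itself; β = 1 is the identity and
β → ∞ a step function.

Decision noise comes in two forms: **fixed** (β = β₀ throughout) and
**volatility-coupled** (β⁽ᵏ⁾ = β₀·exp(−μ̂₃⁽ᵏ⁾)): when the adviser is
believed stable, choices follow beliefs nearly deterministically; when
volatility is high, behaviour becomes exploratory. The coupling uses the
*prediction* μ̂₃ (the previous posterior), again for causal ordering; the
free scale β₀ lets the coupled model nest fixed-noise behaviour when the
volatility estimate is flat. Volatility coupling requires the three-level
filter — it is undefined for the reduced HGF and RW.

Crossing {3-level HGF + volatility noise, 3-level HGF + fixed noise,
reduced HGF, RW} with {integrated, advice-only (ζ = 1), cue-only
(ζ = 0)} gives the 12-model space ([`model_space()`]). The cue-only
models propose no learning about the advice at all; with fixed noise
their likelihood is independent of the perceptual parameters, which are
then held fixed so those cells contribute only their β₀ dimension to the
evidence (making the three fixed-noise cue-only cells evidence-identical,
as they should be).

The Bernoulli log-likelihood is computed in log space directly from the
choice rule, with both log p and log(1 − p) floored at log(1e−16):
mirrored beliefs contribute symmetrically even where the choice
probability saturates at double precision.

# Priors and model inversion

Parameters are estimated in unbounded spaces: log for positive
parameters (κ, β₀, the initial variances), logit for unit-interval
parameters (ϑ, ζ, α, the initial RW value), identity for ω and the
initial means. Prior means (native scale) and variances (estimation
scale): κ 0.5/1, ω −2/100, ϑ 0.5/1, μ₂₀ 0/1, σ₂₀ 1/1, μ₃₀ 1/1, σ₃₀ 1/1;
RW α 0.2/1, v₀ 0.5/1; ζ 0.5/1; β₀ 48/1 (mean log(48) in log space). The
no-volatility HGF fixes κ, ϑ, μ₃₀, σ₃₀ by zero prior variance; the
reduced response models fix ζ structurally at 1 or 0 rather than
transforming a boundary value through the logit.

[`fit_advice_model()`] maximizes the log-joint (Bernoulli likelihood plus
Gaussian log-priors in estimation space) with BFGS, starting from the
prior means; optional multistarts perturb the start by prior-scaled
seeded draws and the best optimum is kept. Invalid parameter regions
evaluate to −∞ (surfaced to the optimizer as a large finite penalty), so
the optimizer backs off rather than crashing. The log model evidence is
the Laplace approximation at the MAP,

F = log p(y, θ*) + (d/2)·log 2π − ½·log det H,

with H the negative Hessian of the log-joint from central finite
differences. A non-positive-definite H is repaired by flooring its
eigenvalues at 1e−8 (flagged); if the determinant is still unusable, F
falls back to the log-joint value and the fit is flagged. Whether the
original analysis included the determinant term is not documented; the
Laplace form is the standard convention and the log-joint fallback is
reported alongside in flagged cases.

# Random-effects model selection

[`bms()`] implements the variational Dirichlet scheme over model
frequencies: iterate g once per subject (the row-softmax of
F added to the digamma correction) and α = α₀ + Σg until the α change
falls below 1e−8 (max 10⁴ iterations), with rows shifted by their
maximum before exponentiation. Exceedance probabilities are Monte Carlo
frequencies of being the maximum of Dirichlet(α) draws (10⁶ by default,
seeded, computed in chunks); for two components the Beta tail is exact
and used as a cross-check in the tests. Family inference sums α over the
partition (the Dirichlet's agglomerative property,
[`family_agglomerate()`]). The analysis prior is α₀ = 1 per model at the
model level; for family comparisons [`run_bms_report()`] rescales α₀
within each family to 1/(family size), giving every family equal prior
mass regardless of how many models it contains (toggleable via
`equal_family_prior`) — the original analysis does not state its family
prior, so both behaviours are available.

# Recovery studies

**Parameter recovery.** Simulated subjects from the winning model class
(3-level HGF, integrated information, volatility-coupled noise) with ζ
and ω drawn from their priors truncated to plausible behavioural ranges
(ζ ∈ [0.1, 0.9]; ω ∈ [−6, −1], spanning the empirically typical range —
the upper end is bounded away from 0 because the forward filter becomes
unstable there; a draw whose forward simulation still triggers the
level-3 precision rejection is resampled) and all other parameters at
prior means. MAP estimates
recover both parameters well (the acceptance suite requires Pearson
r ≥ 0.6 for ζ and ≥ 0.5 for ω over 40 subjects).

**Model recovery.** Twenty datasets per generating model for each of the
four perceptual/noise combinations under the integrated response model,
parameters at prior means, responses contaminated by decision noise (a
50/50 lapse mixture, rate 0.1 by default — the exact form of the noise
used in the original simulations is not recoverable, and the rate is
exposed in the configuration), then refitted with all four candidates;
the per-dataset winner is the highest evidence (for a single dataset
this coincides with the highest exceedance probability), yielding a
confusion matrix, with pooled per-generator BMS reported secondarily.

A finding the recovery suite makes explicit: under these generating
conditions the confusion matrix does *not* show diagonal dominance —
the Rescorla–Wagner candidate is selected for the large majority of
datasets whatever the generator. The cause is structural, not an
optimization failure (multistart changes nothing and within
equal-dimension pairs the ordering is correct, e.g. the
volatility-coupled model beats its fixed-noise twin on
volatility-generated data). At the prior-mean decision-noise scale
(β₀ = 48) choices are near-deterministic threshold readouts of the
integrated belief, so any reasonable reliability tracker — including a
fitted RW — reproduces almost the entire choice sequence (191/192
identical modal choices in a probe comparison), leaving likelihood gaps
of ~1–2 nats between the nine-parameter HGF models and the
four-parameter RW model; the Laplace Occam penalty then decides in
favour of parsimony. The same compression makes the volatility-coupled
response family recoverable only partially: fixed-noise cohorts are
correctly assigned to the decision-noise family, but volatility-coupled
cohorts are absorbed by it too, because the RW cells of the model space
carry most of the posterior assignment mass. These synthetic-recovery
limits delimit what the pipeline can conclude from data generated under
this design; with human data, where choices are noisier and beliefs are
probed at rating trials, the identifiability trade-offs differ.

**Rating validation.** Each subject's coded ratings (helpful 1,
uninformative 0.5, misleading 0) are regressed on the model's predicted
reliability at the probe trials; the per-subject slopes go into a
second-level one-sample t-test. Ratings generated from the agent's own
discretized beliefs validate strongly; shuffled ratings do not.

# Numerical choices and problem sizes

* Optimizer: BFGS with `reltol` 1e−8, max 500 iterations; fits are
  deterministic given the seed.
* Likelihood floors: log-probabilities at log(1e−16); Monte Carlo
  exceedance in chunks of 2.5e5 draws.
* Grid oracle: 81 × 61 grid over x₂ ∈ [−8, 8], x₃ ∈ [−4, 6] — wide
  enough that prior-mean trajectories stay far from the edges.
* The test suite runs the recovery studies at the scales stated above
  (40 subjects; 20 datasets per generator; two 16-subject cohorts for
  the response-family comparison), chosen to match the original
  simulation study's scale while keeping the suite comfortably
  reproducible on a single CPU.

# Known limitations

* The exact printed forms of some update and response equations are
  illegible in the source material (equation images); the standard
  binary three-level HGF forms and the exponentiated Luce rule are
  adopted, and the first-level learning rate is defined operationally.
  These choices are exactly testable and oracle-checked, but they are
  reconstructions, not transcriptions.
* The Laplace evidence is a local approximation; strongly multimodal
  posteriors are only partially protected against by multistart.
* No lapse parameter is fitted (only used when generating recovery
  data), no reaction-time modelling, no recursive theory-of-mind states,
  and no protected exceedance probabilities.
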