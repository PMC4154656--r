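# advicehgf

Hierarchical Bayesian modelling of social learning from volatile advice.

## The problem

In many social exchanges we must decide whether to trust a recommendation
whose source has its own — possibly shifting — agenda. `advicehgf`
implements a complete modelling pipeline for a two-player economic game
that isolates this problem: on each of 192 trials a *player* predicts the
outcome of a binary lottery (blue vs. green) given

* a **non-social cue**: a pie chart showing the true outcome probability
  (one of 75:25, 65:35, 55:45, 45:55, 35:65, 25:75), and
* **social advice** from an *adviser* who privately receives information
  that is correct 80% of the time, but whose monetary incentives to pass
  it on truthfully or invert it change as the player's score moves through
  the adviser's own reward ranges (gold 35–50, silver 95–110 points).

The player must therefore infer not only *how accurate* the advice
currently is, but *how quickly the adviser's intentions are changing* —
the volatility of the social context. The package is aimed at
computational cognitive modellers and computational psychiatrists who
want to simulate this paradigm, fit competing learning models to choice
data, and run the associated model-comparison and recovery machinery.

## Models

**Perceptual models** describe trial-wise belief updating from the binary
advice accuracy u⁽ᵏ⁾:

* a **3-level Hierarchical Gaussian Filter** (HGF): level 1 is the advice
  accuracy, level 2 the adviser's tendency x₂ to give accurate advice
  (probability σ(x₂)), level 3 the log-volatility x₃ of that tendency.
  Updates are precision-weighted prediction errors; the level-2 step size
  is exp(κx₃ + ω) and level 3 performs a random walk with variance ϑ;
* a **reduced 2-level HGF** with the volatility level frozen (no
  hierarchical learning);
* **Rescorla–Wagner**: v⁽ᵏ⁾ = v⁽ᵏ⁻¹⁾ + α(u⁽ᵏ⁾ − v⁽ᵏ⁻¹⁾), a fixed
  learning rate.

**Response models** map beliefs to the probability of following the
advice. The integrated belief is b = ζ·m + (1 − ζ)·c, where m is the
predicted advice reliability, c the pie-chart probability of the advised
colour and ζ the advice weight (ζ = 1: advice only; ζ = 0: cue only).
Choice probabilities follow the exponentiated Luce rule
p(follow) = b^β / (b^β + (1 − b)^β), with decision noise either **fixed**
(β = β₀) or **volatility-coupled** (β⁽ᵏ⁾ = β₀·exp(−μ̂₃⁽ᵏ⁾): the more
stable the adviser is believed to be, the more deterministic the
belief-to-choice mapping). Crossing these factors yields a 12-model
space.

Models are inverted by MAP estimation under the study's priors (BFGS
quasi-Newton, multistart optional), with the log model evidence
approximated by a Laplace expansion around the MAP. Group-level inference
uses random-effects Bayesian model selection — a variational Dirichlet
posterior over model frequencies with exceedance probabilities — and
family-level inference via the Dirichlet's agglomerative property.

## Worked example

```r
library(advicehgf)

# simulate one player (3-level HGF, integrated information,
# volatility-coupled decision noise) facing an incentive-switching adviser
sched <- make_task_schedule(task_config(seed = 42))
dat   <- simulate_player(sched, advice_model("hgf3", "integrated", "volatility"),
                         xi = 0.1, seed = 5)
mean(dat$correct[!dat$is_rating])   # prediction accuracy
#> [1] 0.6770833

# fit the generating model and inspect the MAP estimates
fit <- fit_advice_model(dat, advice_model("hgf3", "integrated", "volatility"),
                        seed = 2)
fit
#> <advice_fit> model hgf3_vol_integrated
#>   log-joint at MAP: -78.8081   log evidence (Laplace): -76.4348
#>   MAP estimates (native space):
#>   kappa   omega   theta   mu2_0   sa2_0   mu3_0   sa3_0    zeta   beta0
#>  0.1768 -1.3660  0.2854  0.1405  0.9512  1.8104  0.9541  0.5203 21.3679
```

The fitted `zeta` near 0.5 says this synthetic player weighted advice and
pie chart about equally; `omega` and `theta` control how fast the
reliability and volatility beliefs move, and the `evidence` value is what
enters Bayesian model selection. `plot(fit)` shows the belief trajectory;
`coef()`, `logLik()`, `predict()`, `residuals()` and `simulate()` behave
as for other R model objects.

Group-level analysis of a simulated cohort:

```r
coh <- simulate_cohort(16, strategy_mix = c(helpful = 4, uninformative = 3,
                                            incentive_switching = 9),
                       model_mix = c(hgf3_vol_integrated = 1), seed = 1)
report <- run_cohort_pipeline(coh, seed = 1)   # 12 fits per subject + BMS
report$winner
```

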