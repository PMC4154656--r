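#' Predicted advice reliability
#'
#' The social source of information entering the response model: the
#' player's prediction, before seeing the trial outcome, that the current
#' advice is accurate. For the HGF variants this is the logistic sigmoid of
#' the predicted level-2 tendency (the posterior carried over from the
#' previous trial); for the Rescorla-Wagner model it is the pre-update
#' value.
#'
#' @param trajectory A `belief_trajectory` from [filter_sequence()].
#' @return Numeric vector of probabilities, one per trial.
#' @export
predicted_advice_reliability <- function(trajectory) {
  if (identical(attr(trajectory, "perceptual"), "rw")) trajectory$vhat
  else trajectory$muhat1
}

#' Integrated belief that the advice is accurate
#'
#' Convex combination of the social estimate `m` (predicted advice
#' reliability) and the non-social cue `c` (the pie-chart probability of
#' the advised colour), weighted by the advice weight `zeta`:
#' `b = zeta * m + (1 - zeta) * c`. `zeta = 1` reduces to the advice-only
#' model, `zeta = 0` to the cue-only model.
#'
#' @param m Predicted advice reliability in (0, 1).
#' @param c Cue probability of the advised colour in (0, 1).
#' @param zeta Advice weight in \[0, 1\].
#' @return Integrated belief, same length as `m`.
#' @export
integrated_belief <- function(m, c, zeta) {
  stopifnot(zeta >= 0, zeta <= 1)
  zeta * m + (1 - zeta) * c
}

#' Trial-wise decision temperature
#'
#' Under fixed decision noise the inverse temperature is a constant
#' `beta0`. Under the volatility-coupled response model it is
#' `beta0 * exp(-muhat3)`, so that a lower predicted adviser volatility
#' yields a steeper (more deterministic) belief-to-response mapping.
#'
#' @param trajectory A `belief_trajectory` (needed for the volatility
#'   variant, which requires the three-level filter).
#' @param beta0 Decision-noise scale (> 0).
#' @param noise `"fixed"` or `"volatility"`.
#' @return Positive vector of per-trial inverse temperatures.
#' @export
decision_temperature <- function(trajectory, beta0,
                                 noise = c("fixed", "volatility")) {
  noise <- match.arg(noise)
  stopifnot(beta0 > 0)
  if (noise == "fixed")
    return(rep(beta0, nrow(trajectory)))
  if (!identical(attr(trajectory, "perceptual"), "hgf3"))
    stop("volatility-coupled decision noise requires the three-level HGF")
  beta0 * exp(-trajectory$muhat3)
}

#' Probability of following the advice
#'
#' Exponentiated Luce choice rule,
#' `p(y = 1) = b^beta / (b^beta + (1 - b)^beta)`: a sigmoid that maps the
#' unit interval onto itself, approaching a step function at `b = 0.5` as
#' `beta` grows and the identity at `beta = 1`.
#'
#' @param b Integrated belief in (0, 1).
#' @param beta Inverse decision temperature (> 0).
#' @return Probability of taking the advice.
#' @export
#' @examples
#' choice_probability(0.7, 4.86)  # ~0.984
choice_probability <- function(b, beta) {
  # computed as plogis(beta * logit(b)) for numerical stability
  stats::plogis(beta * stats::qlogis(b))
}

#' Lapse-contaminated choice probability
#'
#' Mixture of the model's choice probability with an unbiased coin,
#' `p' = (1 - xi) * p + xi / 2`. Used only to generate synthetic datasets
#' with realistic decision noise for recovery studies; the lapse rate is
#' never a fitted parameter.
#'
#' @param p Choice probability.
#' @param xi Lapse probability in \[0, 1\].
#' @return Contaminated probability.
#' @export
noisy_choice_probability <- function(p, xi) {
  stopifnot(xi >= 0, xi <= 1)
  (1 - xi) * p + xi * 0.5
}

## Lean filter for the fitter's objective: returns only the per-trial
## predictions needed by the response models (muhat1/vhat and muhat3),
## avoiding data-frame construction; NULL signals the level-3 precision
## rejection.
filter_lean <- function(u, perceptual, params) {
  n <- length(u)
  if (perceptual == "rw") {
    v <- numeric(n + 1)
    v[1] <- params$v_0
    a <- params$alpha
    for (k in seq_len(n)) v[k + 1] <- v[k] + a * (u[k] - v[k])
    return(list(m = v[seq_len(n)], muhat3 = NULL))
  }
  kappa <- params$kappa; omega <- params$omega; theta <- params$theta
  freeze3 <- perceptual == "hgf2"
  mu2 <- params$mu2_0; sa2 <- params$sa2_0
  mu3 <- params$mu3_0; sa3 <- params$sa3_0
  m <- numeric(n); mh3 <- numeric(n)
  for (k in seq_len(n)) {
    mh1 <- 1 / (1 + exp(-mu2))
    vhat2 <- exp(kappa * mu3 + omega)
    tot2 <- sa2 + vhat2
    mh3[k] <- mu3
    m[k] <- mh1
    delta1 <- u[k] - mh1
    pi2 <- 1 / tot2 + mh1 * (1 - mh1)
    mu2_new <- mu2 + delta1 / pi2
    sa2_new <- 1 / pi2
    if (!freeze3) {
      delta2 <- (sa2_new + (mu2_new - mu2)^2) / tot2 - 1
      w2 <- vhat2 / tot2
      pi3 <- 1 / (sa3 + theta) +
        (kappa^2 / 2) * w2 * (w2 + (2 * w2 - 1) * delta2)
      if (!is.finite(pi3) || pi3 <= 0) return(NULL)
      mu3 <- mu3 + (kappa / 2) * (w2 / pi3) * delta2
      sa3 <- 1 / pi3
    }
    mu2 <- mu2_new; sa2 <- sa2_new
  }
  list(m = m, muhat3 = mh3)
}

## Bernoulli log-likelihood on a precomputed input context
## (ctx: list with u, c, y from subject_inputs). -Inf on rejection.
loglik_lean <- function(ctx, model, params) {
  keep <- !is.na(ctx$y)
  if (!any(keep)) return(0)
  fl <- filter_lean(ctx$u, model$perceptual, params)
  if (is.null(fl)) return(-Inf)
  zeta <- switch(model$info, integrated = params$zeta,
                 advice_only = 1, cue_only = 0)
  b <- zeta * fl$m + (1 - zeta) * ctx$c
  beta <- if (model$noise == "volatility")
    params$beta0 * exp(-fl$muhat3) else params$beta0
  eta <- (beta * log(b / (1 - b)))[keep]
  lp1 <- pmax(-log1p(exp(-eta)), log(1e-16))
  lp0 <- pmax(-log1p(exp(eta)), log(1e-16))
  y <- ctx$y[keep]
  sum(y * lp1 + (1 - y) * lp0)
}

# Full belief-to-choice chain for one subject under one model.
# Returns per-trial m, b, beta, p aligned with the modeled (prediction)
# trials of the dataset, plus the trajectory.
response_chain <- function(data, model, params) {
  inp <- subject_inputs(data)
  if (model$perceptual == "rw") {
    pp <- params[c("alpha", "v_0")]
  } else {
    pp <- params[c("kappa", "omega", "theta", "mu2_0", "sa2_0",
                   "mu3_0", "sa3_0")]
  }
  traj <- filter_sequence(inp$u, model$perceptual, pp)
  m <- predicted_advice_reliability(traj)
  zeta <- switch(model$info,
                 integrated = params$zeta,
                 advice_only = 1,
                 cue_only = 0)
  b <- integrated_belief(m, inp$c, zeta)
  beta <- decision_temperature(traj, params$beta0, model$noise)
  p <- choice_probability(b, beta)
  list(trajectory = traj, m = m, b = b, beta = beta, p = p,
       y = inp$y, u = inp$u, c = inp$c)
}

#' Bernoulli log-likelihood of a subject's responses
#'
#' Sums `y * log(p) + (1 - y) * log(1 - p)` over the modeled prediction
#' trials, where `p` is the trial-wise probability of following the advice
#' produced by the full chain (perceptual filter, information integration,
#' decision temperature, choice rule). Trials with a missing response are
#' skipped. Probabilities are clamped to `[1e-16, 1 - 1e-16]` before
#' taking logs.
#'
#' @param data An `advice_subject` data frame (see [simulate_player()] and
#'   [read_subject_csv()]).
#' @param model An [advice_model()] specification.
#' @param params Named list of native-space parameters for that model.
#' @return The log-likelihood (0 for a dataset with no observed responses).
#' @export
response_loglik <- function(data, model, params) {
  ch <- response_chain(data, model, params)
  keep <- !is.na(ch$y)
  if (!any(keep)) return(0)
  ## Bernoulli terms in log space: log p and log(1 - p) computed directly
  ## from the choice rule so mirrored beliefs contribute symmetrically,
  ## with both floored at log(1e-16) against saturation.
  eta <- (ch$beta * stats::qlogis(ch$b))[keep]
  lp1 <- pmax(stats::plogis(eta, log.p = TRUE), log(1e-16))
  lp0 <- pmax(stats::plogis(-eta, log.p = TRUE), log(1e-16))
  y <- ch$y[keep]
  sum(y * lp1 + (1 - y) * lp0)
}
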