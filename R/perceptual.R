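#' Logistic sigmoid
#'
#' Maps the real line onto the unit interval, `s(x) = 1 / (1 + exp(-x))`.
#' Used to link the unbounded tendency state of the learning hierarchy to a
#' probability of accurate advice.
#'
#' @param x Numeric vector.
#' @return Numeric vector of probabilities strictly in (0, 1).
#' @export
#' @examples
#' logistic_sigmoid(0)    # 0.5
#' logistic_sigmoid(2)    # ~0.881
logistic_sigmoid <- function(x) {
  stats::plogis(x)
}

#' Prior-mean parameters of the three-level HGF
#'
#' Convenience constructor for the perceptual parameter list used by
#' [hgf_filter()]: coupling strength `kappa`, tonic log-volatility `omega`,
#' meta-volatility `theta`, and the initial beliefs (mean and variance) at
#' levels 2 and 3.
#'
#' @param kappa Coupling between levels 2 and 3 (> 0).
#' @param omega Tonic component of the level-2 log-volatility.
#' @param theta Meta-volatility: variance of the level-3 random walk (> 0).
#' @param mu2_0,sa2_0 Initial level-2 mean and variance.
#' @param mu3_0,sa3_0 Initial level-3 mean and variance.
#' @return Named list of parameters.
#' @export
hgf_params <- function(kappa = 0.5, omega = -2, theta = 0.5,
                       mu2_0 = 0, sa2_0 = 1, mu3_0 = 1, sa3_0 = 1) {
  stopifnot(kappa > 0, theta > 0, sa2_0 > 0, sa3_0 > 0)
  list(kappa = kappa, omega = omega, theta = theta,
       mu2_0 = mu2_0, sa2_0 = sa2_0, mu3_0 = mu3_0, sa3_0 = sa3_0)
}

#' Rescorla-Wagner parameters
#'
#' @param alpha Learning rate in (0, 1).
#' @param v_0 Initial value of the advice (probability of accurate advice).
#' @return Named list of parameters.
#' @export
rw_params <- function(alpha = 0.2, v_0 = 0.5) {
  stopifnot(alpha > 0, alpha < 1, v_0 > 0, v_0 < 1)
  list(alpha = alpha, v_0 = v_0)
}

# Condition signalled when a parameter vector drives the level-3 posterior
# precision non-positive; the fitter maps it to log-joint = -Inf.
hgf_reject <- function(msg) {
  stop(structure(class = c("hgf_rejection", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Single update of the three-level binary HGF
#'
#' One trial of the variational belief update for the binary hierarchical
#' Gaussian filter. The state tracks the posterior mean and variance of the
#' adviser's tendency to give accurate advice (level 2) and of the
#' log-volatility of that tendency (level 3). Predictions (hatted
#' quantities) are formed before the input is seen; the update weights the
#' value prediction error `delta1` and the volatility prediction error
#' `delta2` by precision ratios.
#'
#' @param state Named list with elements `mu2`, `sa2`, `mu3`, `sa3`.
#' @param u Binary input: 1 if the advice was accurate on this trial.
#' @param params Parameter list from [hgf_params()].
#' @param freeze3 If `TRUE`, level 3 is held at its current value (the
#'   reduced, no-volatility filter).
#' @return Updated state list; the per-trial quantities (`muhat1`, `pihat2`,
#'   `delta1`, `delta2`, `w2`, ...) are attached as list elements prefixed
#'   with `t_`.
#' @export
hgf_step <- function(state, u, params, freeze3 = FALSE) {
  kappa <- params$kappa; omega <- params$omega; theta <- params$theta
  mu2 <- state$mu2; sa2 <- state$sa2; mu3 <- state$mu3; sa3 <- state$sa3

  ## prediction step
  muhat1 <- logistic_sigmoid(mu2)
  vhat2 <- exp(kappa * mu3 + omega)
  pihat2 <- 1 / (sa2 + vhat2)
  pihat3 <- 1 / (sa3 + theta)

  ## level-2 update: precision-weighted value prediction error
  delta1 <- u - muhat1
  pi2 <- pihat2 + muhat1 * (1 - muhat1)
  mu2_new <- mu2 + delta1 / pi2
  sa2_new <- 1 / pi2

  ## level-3 update: volatility prediction error
  delta2 <- (sa2_new + (mu2_new - mu2)^2) / (sa2 + vhat2) - 1
  w2 <- vhat2 / (sa2 + vhat2)
  if (freeze3) {
    pi3 <- 1 / sa3
    mu3_new <- mu3
    sa3_new <- sa3
  } else {
    pi3 <- pihat3 + (kappa^2 / 2) * w2 * (w2 + (2 * w2 - 1) * delta2)
    if (!is.finite(pi3) || pi3 <= 0)
      hgf_reject("level-3 posterior precision is not positive")
    mu3_new <- mu3 + (kappa / 2) * (w2 / pi3) * delta2
    sa3_new <- 1 / pi3
  }

  list(mu2 = mu2_new, sa2 = sa2_new, mu3 = mu3_new, sa3 = sa3_new,
       t_muhat1 = muhat1, t_muhat2 = mu2, t_muhat3 = mu3,
       t_vhat2 = vhat2, t_pihat2 = pihat2, t_pihat3 = pihat3,
       t_delta1 = delta1, t_delta2 = delta2, t_w2 = w2, t_pi3 = pi3)
}

#' Single Rescorla-Wagner update
#'
#' `v' = v + alpha * (u - v)`: the estimated value of the advice moves
#' toward the observed accuracy by a constant fraction `alpha`.
#'
#' @param v Current value estimate in (0, 1).
#' @param u Binary input (advice accuracy).
#' @param alpha Learning rate in (0, 1).
#' @return Updated value.
#' @export
rw_step <- function(v, u, alpha) {
  v + alpha * (u - v)
}

#' Run a belief-updating filter over a trial sequence
#'
#' Folds the chosen perceptual model over a binary input sequence of advice
#' accuracies and records the trial-wise belief trajectory. Hatted columns
#' are predictions formed before each trial's input; unhatted columns are
#' posteriors after the update.
#'
#' @param u Binary vector of advice accuracies (1 = advice matched outcome).
#' @param perceptual One of `"hgf3"` (three-level filter), `"hgf2"`
#'   (reduced filter with level 3 frozen at its initial value), `"rw"`
#'   (Rescorla-Wagner).
#' @param params Parameter list ([hgf_params()] or [rw_params()]); defaults
#'   to the prior means.
#' @return A data frame of class `belief_trajectory` with one row per
#'   trial. For HGF variants the columns are `muhat1`, `muhat2`, `muhat3`,
#'   `mu1`, `mu2`, `mu3`, `sa2`, `sa3`, `pihat2`, `pihat3`, `delta1`,
#'   `delta2`, `w2`, `pi3`; for the RW model, `vhat` (pre-update value,
#'   the prediction used by the response model), `v` and `delta1`.
#' @export
#' @examples
#' u <- rbinom(50, 1, 0.8)
#' traj <- filter_sequence(u, "hgf3")
#' head(traj)
filter_sequence <- function(u, perceptual = c("hgf3", "hgf2", "rw"),
                            params = NULL) {
  perceptual <- match.arg(perceptual)
  stopifnot(all(u %in% c(0, 1)))
  n <- length(u)

  if (perceptual == "rw") {
    if (is.null(params)) params <- rw_params()
    v <- numeric(n + 1)
    v[1] <- params$v_0
    for (k in seq_len(n)) v[k + 1] <- rw_step(v[k], u[k], params$alpha)
    out <- data.frame(trial = seq_len(n),
                      vhat = v[seq_len(n)], v = v[-1],
                      delta1 = u - v[seq_len(n)])
    attr(out, "perceptual") <- "rw"
    class(out) <- c("belief_trajectory", "data.frame")
    return(out)
  }

  if (is.null(params)) params <- hgf_params()
  freeze3 <- perceptual == "hgf2"
  state <- list(mu2 = params$mu2_0, sa2 = params$sa2_0,
                mu3 = params$mu3_0, sa3 = params$sa3_0)
  cols <- c("muhat1", "muhat2", "muhat3", "mu1", "mu2", "mu3", "sa2", "sa3",
            "pihat2", "pihat3", "delta1", "delta2", "w2", "pi3")
  m <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (k in seq_len(n)) {
    state <- hgf_step(state, u[k], params, freeze3 = freeze3)
    m[k, ] <- c(state$t_muhat1, state$t_muhat2, state$t_muhat3,
                logistic_sigmoid(state$mu2), state$mu2, state$mu3,
                state$sa2, state$sa3,
                state$t_pihat2, state$t_pihat3,
                state$t_delta1, state$t_delta2, state$t_w2, state$t_pi3)
  }
  out <- data.frame(trial = seq_len(n), m)
  attr(out, "perceptual") <- perceptual
  attr(out, "params") <- params
  class(out) <- c("belief_trajectory", "data.frame")
  out
}

#' Trial-wise learning-rate diagnostics
#'
#' The effective first-level learning rate is the realized update of the
#' predicted advice accuracy per unit of value prediction error,
#' `lr1 = (mu1 - muhat1) / delta1` (undefined, and reported as `NA`, when
#' `delta1 = 0`). The third-level learning rate is the coefficient on the
#' volatility prediction error in the level-3 update,
#' `lr3 = (kappa / 2) * w2 / pi3`.
#'
#' @param trajectory A `belief_trajectory` from an HGF variant.
#' @return Data frame with columns `trial`, `lr1`, `lr3`.
#' @export
learning_rates <- function(trajectory) {
  if (identical(attr(trajectory, "perceptual"), "rw"))
    stop("learning-rate diagnostics are defined for the HGF variants")
  kappa <- attr(trajectory, "params")$kappa
  lr1 <- (trajectory$mu1 - trajectory$muhat1) / trajectory$delta1
  lr1[trajectory$delta1 == 0] <- NA_real_
  lr3 <- (kappa / 2) * trajectory$w2 / trajectory$pi3
  data.frame(trial = trajectory$trial, lr1 = lr1, lr3 = lr3)
}
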