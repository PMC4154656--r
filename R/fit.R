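## MAP inversion under the study priors with a quasi-Newton optimizer, and
## Laplace approximation of the log model evidence.

transform_to_est <- function(x, transform) {
  switch(transform,
         identity = x,
         log = {
           if (x <= 0) stop("log transform requires a positive value")
           log(x)
         },
         logit = {
           if (x <= 0 || x >= 1)
             stop("logit transform requires a value strictly in (0, 1)")
           stats::qlogis(x)
         })
}

transform_to_native <- function(x, transform) {
  switch(transform, identity = x, log = exp(x), logit = stats::plogis(x))
}

#' Map parameters between native and estimation space
#'
#' Parameters are optimized in an unbounded estimation space: positive
#' parameters on the log scale, unit-interval parameters on the logit
#' scale, real-valued parameters untransformed. Fixed parameters (zero
#' prior variance) are excluded from the vector.
#'
#' @param params Named list of native-space values (free parameters).
#' @param priors A `prior_spec` from [default_priors()].
#' @return `to_estimation_space()` returns a named numeric vector over the
#'   free parameters; `from_estimation_space()` returns the full named
#'   list of native values, fixed parameters filled in from the priors.
#' @export
to_estimation_space <- function(params, priors) {
  free <- priors[!priors$fixed, ]
  vapply(seq_len(nrow(free)), function(i)
    transform_to_est(params[[free$parameter[i]]], free$transform[i]),
    numeric(1)) |> stats::setNames(free$parameter)
}

#' @rdname to_estimation_space
#' @param theta Named numeric vector in estimation space.
#' @export
from_estimation_space <- function(theta, priors) {
  out <- as.list(priors$mean_native)
  names(out) <- priors$parameter
  free <- priors[!priors$fixed, ]
  for (i in seq_len(nrow(free)))
    out[[free$parameter[i]]] <-
      transform_to_native(theta[[free$parameter[i]]], free$transform[i])
  out
}

prior_mean_est <- function(priors) {
  free <- priors[!priors$fixed, ]
  vapply(seq_len(nrow(free)), function(i)
    transform_to_est(free$mean_native[i], free$transform[i]),
    numeric(1)) |> stats::setNames(free$parameter)
}

#' Prior-mean parameter list of a model
#'
#' @param model An [advice_model()].
#' @return Named list of native-space parameter values at the prior means.
#' @export
prior_mean_params <- function(model) {
  pr <- default_priors(model)
  stats::setNames(as.list(pr$mean_native), pr$parameter)
}

check_native_params <- function(model, params) {
  pr <- default_priors(model)
  missing_par <- setdiff(pr$parameter, names(params))
  ## zeta is structural in the reduced models and may be omitted
  missing_par <- setdiff(missing_par, if (model$info != "integrated") "zeta")
  if (length(missing_par))
    stop("missing parameters for model ", model$label, ": ",
         paste(missing_par, collapse = ", "))
  invisible(TRUE)
}

#' Log-joint density of data and parameters
#'
#' The MAP objective: the Bernoulli response log-likelihood of the model
#' chain plus independent Gaussian log-priors on the free parameters in
#' estimation space. Parameter vectors that drive the filter into an
#' invalid state (non-positive level-3 precision) or produce a non-finite
#' likelihood evaluate to `-Inf` rather than erroring, so the optimizer
#' can back off.
#'
#' @param theta Named numeric vector in estimation space (free parameters).
#' @param data An `advice_subject` data frame.
#' @param model An [advice_model()].
#' @param priors A `prior_spec`; defaults to [default_priors()] of the
#'   model.
#' @return The log-joint value (possibly `-Inf`).
#' @export
log_joint <- function(theta, data, model, priors = default_priors(model)) {
  log_joint_ctx(theta, subject_inputs(data), model, priors)
}

# Same objective on a precomputed input context (hot path for the fitter).
log_joint_ctx <- function(theta, ctx, model, priors) {
  if (any(!is.finite(theta))) return(-Inf)
  free <- priors[!priors$fixed, ]
  mu <- prior_mean_est(priors)
  lp <- sum(stats::dnorm(theta, mu, sqrt(free$var_est), log = TRUE))
  params <- from_estimation_space(theta, priors)
  ll <- tryCatch(loglik_lean(ctx, model, params),
                 error = function(e) -Inf)
  if (!is.finite(ll)) return(-Inf)
  ll + lp
}

#' Fit a model to one subject by MAP estimation
#'
#' Maximizes the log-joint posterior density over the free parameters in
#' estimation space with the BFGS quasi-Newton algorithm. The first start
#' is the prior mean; additional multistarts perturb it by draws from the
#' prior (scaled by `start_sd_scale`) under the given seed, and the best
#' converged optimum is kept. The log model evidence is approximated at
#' the optimum by [laplace_evidence()].
#'
#' @param data An `advice_subject` data frame (from [simulate_player()],
#'   [read_subject_csv()], or assembled via [as_advice_subject()]).
#' @param model An [advice_model()]; default is the three-level HGF with
#'   integrated information and volatility-coupled decision noise.
#' @param priors A `prior_spec`; defaults to the study priors.
#' @param n_starts Number of optimizer starts (>= 1).
#' @param start_sd_scale Multiplier on the prior standard deviation for
#'   the multistart perturbations.
#' @param seed Integer seed controlling the multistart draws.
#' @param control Passed to [stats::optim()].
#' @return An object of class `advice_fit` with components `estimates`
#'   (native space), `theta` (estimation space), `logjoint`, `loglik`,
#'   `evidence` (Laplace log model evidence), `hessian`, `model`,
#'   `priors`, `data`, `optim` diagnostics, and the belief trajectory and
#'   per-trial choice probabilities at the MAP.
#' @export
#' @examples
#' sched <- make_task_schedule(task_config(seed = 7))
#' dat <- simulate_player(sched, advice_model("rw", "integrated"), seed = 7)
#' fit <- fit_advice_model(dat, advice_model("rw", "integrated"))
#' coef(fit)
fit_advice_model <- function(data,
                             model = advice_model("hgf3", "integrated",
                                                  "volatility"),
                             priors = default_priors(model),
                             n_starts = 1, start_sd_scale = 0.5,
                             seed = 1L,
                             control = list(maxit = 500, reltol = 1e-8)) {
  stopifnot(n_starts >= 1)
  inp <- subject_inputs(data)
  if (sum(!is.na(inp$y)) < 1)
    stop("dataset has no modeled trials with an observed response")

  free <- priors[!priors$fixed, ]
  mu0 <- prior_mean_est(priors)
  ctx <- subject_inputs(data)
  negobj <- function(theta) {
    v <- log_joint_ctx(stats::setNames(theta, names(mu0)), ctx, model,
                       priors)
    if (!is.finite(v)) 1e10 else -v
  }

  set.seed(seed)
  starts <- list(mu0)
  if (n_starts > 1)
    for (j in seq_len(n_starts - 1))
      starts[[j + 1]] <- mu0 + stats::rnorm(length(mu0)) *
        sqrt(free$var_est) * start_sd_scale

  best <- NULL
  diagnostics <- list()
  for (j in seq_along(starts)) {
    res <- tryCatch(
      stats::optim(starts[[j]], negobj, method = "BFGS", control = control),
      error = function(e) NULL)
    diagnostics[[j]] <- if (is.null(res)) list(failed = TRUE)
      else list(value = -res$value, convergence = res$convergence,
                counts = res$counts)
    if (!is.null(res) && res$value < 1e9 &&
        (is.null(best) || res$value < best$value)) {
      best <- res
      best$start_index <- j
    }
  }
  if (is.null(best))
    return(structure(list(failed = TRUE, model = model, priors = priors,
                          diagnostics = diagnostics, seed = seed),
                     class = "advice_fit"))

  theta <- stats::setNames(best$par, names(mu0))
  lj <- log_joint_ctx(theta, ctx, model, priors)
  lap <- laplace_evidence(theta, function(th)
    log_joint_ctx(stats::setNames(th, names(mu0)), ctx, model, priors))
  params <- from_estimation_space(theta, priors)
  ch <- response_chain(data, model, params)

  structure(list(
    estimates = params, theta = theta,
    logjoint = lj,
    loglik = response_loglik(data, model, params),
    evidence = lap$F, hessian = lap$H,
    hessian_logdet = lap$logdet, hessian_repaired = lap$repaired,
    evidence_flagged = lap$flagged,
    model = model, priors = priors, data = data,
    trajectory = ch$trajectory,
    fitted = data.frame(trial = subject_inputs(data)$trial,
                        m = ch$m, b = ch$b, beta = ch$beta, p = ch$p,
                        y = ch$y),
    optim = list(convergence = best$convergence, counts = best$counts,
                 start_index = best$start_index,
                 diagnostics = diagnostics),
    n_starts = n_starts, seed = as.integer(seed), failed = FALSE),
    class = "advice_fit")
}

#' Laplace approximation of the log model evidence
#'
#' Gaussian expansion of the log-joint around the MAP:
#' `F = logjoint(theta*) + (d/2) log(2 pi) - (1/2) log det H`, where `H`
#' is the negative Hessian of the log-joint at the optimum, obtained by
#' central finite differences. A non-positive-definite `H` is repaired by
#' clamping its eigenvalues at a small positive floor (flagged in the
#' result); if the determinant is still not finite, `F` falls back to the
#' log-joint value and the result is flagged.
#'
#' @param theta MAP estimate in estimation space.
#' @param fn Log-joint function of the estimation-space vector.
#' @return List with `F`, `H`, `logdet`, `repaired`, `flagged`.
#' @export
laplace_evidence <- function(theta, fn) {
  d <- length(theta)
  lj <- as.numeric(fn(theta))
  if (d == 0)
    return(list(F = lj, H = matrix(0, 0, 0), logdet = 0,
                repaired = FALSE, flagged = FALSE))
  H <- -pracma::hessian(fn, theta)
  H <- (H + t(H)) / 2
  if (any(!is.finite(H)))
    return(list(F = lj, H = H, logdet = NA_real_, repaired = FALSE,
                flagged = TRUE))
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  repaired <- FALSE
  if (any(ev <= 0)) {
    e <- eigen(H, symmetric = TRUE)
    e$values <- pmax(e$values, 1e-8)
    H <- e$vectors %*% diag(e$values, d) %*% t(e$vectors)
    ev <- e$values
    repaired <- TRUE
  }
  logdet <- sum(log(ev))
  if (!is.finite(logdet))
    return(list(F = lj, H = H, logdet = NA_real_, repaired = repaired,
                flagged = TRUE))
  list(F = lj + (d / 2) * log(2 * pi) - logdet / 2,
       H = H, logdet = logdet, repaired = repaired, flagged = FALSE)
}

#' @export
print.advice_fit <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("<advice_fit> FAILED fit for model", x$model$label, "\n")
    return(invisible(x))
  }
  cat("<advice_fit> model ", x$model$label, "\n", sep = "")
  cat("  log-joint at MAP: ", format(x$logjoint, digits = 6),
      "   log evidence (Laplace): ", format(x$evidence, digits = 6),
      "\n", sep = "")
  cat("  MAP estimates (native space):\n")
  est <- unlist(x$estimates[names(x$theta)])
  print(round(est, 4))
  invisible(x)
}

#' @export
coef.advice_fit <- function(object, space = c("native", "estimation"), ...) {
  space <- match.arg(space)
  if (space == "estimation") return(object$theta)
  unlist(object$estimates[names(object$theta)])
}

#' @export
logLik.advice_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta),
            nobs = sum(!is.na(object$fitted$y)), class = "logLik")
}

#' @export
summary.advice_fit <- function(object, ...) {
  est <- coef(object)
  se <- rep(NA_real_, length(est))
  if (!is.null(object$hessian) && nrow(object$hessian) == length(est)) {
    v <- tryCatch(diag(solve(object$hessian)), error = function(e) NULL)
    if (!is.null(v) && all(v > 0)) {
      ## delta method back to native space
      grad <- vapply(seq_along(est), function(i) {
        tr <- object$priors$transform[match(names(est)[i],
                                            object$priors$parameter)]
        th <- object$theta[i]
        switch(tr, identity = 1, log = exp(th),
               logit = stats::plogis(th) * (1 - stats::plogis(th)))
      }, numeric(1))
      se <- sqrt(v) * grad
    }
  }
  out <- list(model = object$model,
              coefficients = cbind(Estimate = est, `Std.Error` = se),
              loglik = object$loglik, evidence = object$evidence,
              n_trials = sum(!is.na(object$fitted$y)),
              convergence = object$optim$convergence)
  class(out) <- "summary.advice_fit"
  out
}

#' @export
print.summary.advice_fit <- function(x, ...) {
  cat("Model:", x$model$label, "\n")
  cat("Modeled trials:", x$n_trials,
      "  log-likelihood:", format(x$loglik, digits = 6),
      "  log evidence:", format(x$evidence, digits = 6), "\n\n")
  printCoefmat(x$coefficients, na.print = "-")
  invisible(x)
}

#' @export
predict.advice_fit <- function(object,
                               type = c("response", "belief",
                                        "temperature"), ...) {
  type <- match.arg(type)
  switch(type, response = object$fitted$p, belief = object$fitted$b,
         temperature = object$fitted$beta)
}

#' @export
residuals.advice_fit <- function(object, ...) {
  object$fitted$y - object$fitted$p
}

#' @export
simulate.advice_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fitted$p
  out <- replicate(nsim, as.integer(stats::runif(length(p)) < p),
                   simplify = FALSE)
  names(out) <- paste0("sim_", seq_len(nsim))
  as.data.frame(out)
}

#' Plot the fitted belief trajectory
#'
#' Two stacked panels: the predicted advice reliability with the observed
#' advice accuracies and follow/defy responses, and (for the three-level
#' HGF) the predicted log-volatility of the adviser's intentions.
#'
#' @param x An `advice_fit`.
#' @param ... Ignored.
#' @export
plot.advice_fit <- function(x, ...) {
  traj <- x$trajectory
  is_hgf <- !identical(attr(traj, "perceptual"), "rw")
  op <- graphics::par(mfrow = c(if (is_hgf) 2 else 1, 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  m <- predicted_advice_reliability(traj)
  u <- subject_inputs(x$data)$u
  graphics::plot(seq_along(m), m, type = "l", ylim = c(0, 1),
                 xlab = "prediction trial", ylab = "P(advice accurate)",
                 main = x$model$label)
  graphics::points(seq_along(u), u, pch = 3, cex = 0.4, col = "grey40")
  graphics::points(seq_along(u), x$fitted$y, pch = 1, cex = 0.4,
                   col = "steelblue")
  if (is_hgf) {
    graphics::plot(traj$trial, traj$muhat3, type = "l",
                   xlab = "prediction trial",
                   ylab = "predicted log-volatility")
  }
  invisible(x)
}
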