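# Independent oracles used across tests.

# Exact sequential Bayesian filter for the hierarchical generative model on
# a discretized (x2, x3) grid: x3' ~ N(x3, theta), x2' ~ N(x2,
# exp(kappa * x3' + omega)), u ~ Bernoulli(sigmoid(x2')). Provides
# grid-exact predicted advice accuracies to compare against the
# variational filter.
grid_filter_oracle <- function(u, params,
                               x2 = seq(-8, 8, length.out = 81),
                               x3 = seq(-4, 6, length.out = 61)) {
  s <- function(x) 1 / (1 + exp(-x))
  P <- outer(stats::dnorm(x2, params$mu2_0, sqrt(params$sa2_0)),
             stats::dnorm(x3, params$mu3_0, sqrt(params$sa3_0)))
  P <- P / sum(P)
  T3 <- outer(x3, x3, function(a, b) stats::dnorm(b, a, sqrt(params$theta)))
  T3 <- T3 / rowSums(T3)
  T2 <- lapply(seq_along(x3), function(j) {
    M <- outer(x2, x2, function(a, b)
      stats::dnorm(b, a, sqrt(exp(params$kappa * x3[j] + params$omega))))
    M / rowSums(M)
  })
  muhat1 <- numeric(length(u))
  for (k in seq_along(u)) {
    M <- P %*% T3                                    # old x2 rows, new x3 cols
    B <- sapply(seq_along(x3), function(j) crossprod(T2[[j]], M[, j]))
    muhat1[k] <- sum(rowSums(B) * s(x2))
    lik <- if (u[k] == 1) s(x2) else 1 - s(x2)
    P <- B * lik
    P <- P / sum(P)
  }
  muhat1
}

# Deterministic reversal schedule of advice accuracies: blocks of
# high-accuracy advice followed by low-accuracy advice.
reversal_inputs <- function(n_per_phase = 120, p_high = 0.8, p_low = 0.2,
                            seed = 11) {
  set.seed(seed)
  c(stats::rbinom(n_per_phase, 1, p_high),
    stats::rbinom(n_per_phase, 1, p_low))
}

# Small complete subject table built directly (no simulator) for
# likelihood tests.
toy_subject <- function(u = c(1, 1, 0), c_adv = c(0.75, 0.55, 0.35),
                        y = c(1, 1, 0)) {
  n <- length(u)
  advice <- rep("blue", n)
  outcome <- ifelse(u == 1, "blue", "green")
  response <- ifelse(y == 1, "blue", "green")
  response[is.na(y)] <- NA_character_
  as_advice_subject(data.frame(
    trial = seq_len(n), is_rating = FALSE, cue_p_blue = c_adv,
    advice_color = advice, outcome_color = outcome,
    response_color = response, rating_value = NA_real_,
    stringsAsFactors = FALSE))
}
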