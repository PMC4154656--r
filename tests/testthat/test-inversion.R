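test_that("estimation-space transforms round-trip and hit known values", {
  mod <- advice_model("hgf3", "integrated", "volatility")
  priors <- default_priors(mod)
  params <- prior_mean_params(mod)
  params$zeta <- 0.5
  params$kappa <- 1
  theta <- to_estimation_space(params, priors)
  expect_equal(unname(theta["zeta"]), 0)
  expect_equal(unname(theta["kappa"]), 0)         # log(1)
  expect_equal(unname(theta["omega"]), -2)        # identity
  back <- from_estimation_space(theta, priors)
  for (nm in names(params)) expect_equal(back[[nm]], params[[nm]])

  bad <- params; bad$zeta <- 1
  expect_error(to_estimation_space(bad, priors), "strictly")
})

test_that("fixed parameters are excluded from the estimation vector", {
  mod2 <- advice_model("hgf2", "integrated", "fixed")
  pr2 <- default_priors(mod2)
  free <- names(to_estimation_space(prior_mean_params(mod2), pr2))
  expect_setequal(free, c("omega", "mu2_0", "sa2_0", "zeta", "beta0"))

  cue <- advice_model("rw", "cue_only", "fixed")
  expect_setequal(names(to_estimation_space(prior_mean_params(cue),
                                            default_priors(cue))),
                  "beta0")
  # the 3x2x2 tree has exactly 12 cells and one nine-parameter model
  expect_length(model_space(), 12)
  win <- advice_model("hgf3", "integrated", "volatility")
  expect_length(to_estimation_space(prior_mean_params(win),
                                    default_priors(win)), 9)
})

test_that("the log-joint separates into likelihood and Gaussian prior", {
  dat <- toy_subject(u = c(1, 1, 0), c_adv = c(0.8, 0.6, 0.3),
                     y = c(1, 1, 0))
  mod <- advice_model("rw", "cue_only", "fixed")
  priors <- default_priors(mod)
  theta <- c(beta0 = 0)  # log-space value -> beta0 = 1, so p = c
  lp_expect <- dnorm(0, log(48), 1, log = TRUE)
  expect_equal(log_joint(theta, dat, mod, priors),
               (log(0.8) + log(0.6) + log(0.7)) + lp_expect,
               tolerance = 1e-10)
  # non-finite parameter vectors are vetoed, not raised
  expect_identical(log_joint(c(beta0 = NaN), dat, mod, priors), -Inf)
})

test_that("with no informative data the log-joint peaks at the prior mean", {
  dat <- toy_subject(u = c(1, 0), c_adv = c(0.6, 0.4), y = c(NA, NA))
  mod <- advice_model("rw", "integrated", "fixed")
  priors <- default_priors(mod)
  mu <- advicehgf:::prior_mean_est(priors)
  lj0 <- log_joint(mu, dat, mod, priors)
  set.seed(10)
  for (i in 1:20) {
    expect_lt(log_joint(mu + rnorm(length(mu), 0, 0.3), dat, mod, priors),
              lj0)
  }
})

test_that("MAP matches a dense grid search in low dimension", {
  sched <- make_task_schedule(task_config(seed = 66))
  gen <- advice_model("rw", "cue_only", "fixed")
  gen_par <- prior_mean_params(gen)
  gen_par$beta0 <- 4
  dat <- simulate_player(sched, gen, params = gen_par, seed = 7)
  fit <- fit_advice_model(dat, gen)
  grid <- seq(log(0.5), log(60), length.out = 400)
  lj <- vapply(grid, function(g)
    log_joint(c(beta0 = g), dat, gen, default_priors(gen)), numeric(1))
  expect_lt(abs(fit$theta[["beta0"]] - grid[which.max(lj)]),
            diff(grid[1:2]) * 2)
})

test_that("persistent following pushes the cue-only noise estimate upward", {
  # a player who always follows regardless of the cue forces beta0 down
  # (noisier than prior); one who follows exactly when the cue favours the
  # advice pushes beta0 up. Directional check against the prior mean in
  # estimation space.
  sched <- make_task_schedule(task_config(seed = 67))
  mod <- advice_model("rw", "cue_only", "fixed")
  dat <- simulate_player(sched, advice_model("rw", "integrated"), seed = 2)
  raw <- dat[, c("trial", "is_rating", "cue_p_blue", "advice_color",
                 "outcome_color", "response_color", "rating_value")]
  pred <- !raw$is_rating
  follow_cue <- ifelse(raw$cue_p_blue >= 0.5, "blue", "green")
  raw$response_color[pred] <- follow_cue[pred]
  strict <- as_advice_subject(raw)
  fit_strict <- fit_advice_model(strict, mod)
  expect_gt(fit_strict$estimates$beta0, 48)
})

test_that("fits are deterministic given the seed", {
  sched <- make_task_schedule(task_config(seed = 68))
  mod <- advice_model("rw", "integrated", "fixed")
  dat <- simulate_player(sched, mod, seed = 3)
  f1 <- fit_advice_model(dat, mod, n_starts = 3, seed = 11)
  f2 <- fit_advice_model(dat, mod, n_starts = 3, seed = 11)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$evidence, f2$evidence)
})

test_that("Laplace evidence reproduces conjugate closed forms", {
  # data-free: posterior equals prior, evidence integrates to exactly 1
  fn_prior <- function(th) dnorm(th, 0, 1, log = TRUE) +
    dnorm(th, 0, sqrt(2), log = TRUE) * 0
  lap <- laplace_evidence(c(x = 0), function(th)
    dnorm(th[1], 0, 1, log = TRUE))
  expect_equal(lap$F, 0, tolerance = 1e-6)

  # standard-normal prior x Gaussian likelihood exp(-theta^2/2):
  # the integral is 1/sqrt(2)
  fn <- function(th) dnorm(th[1], 0, 1, log = TRUE) - th[1]^2 / 2
  lap2 <- laplace_evidence(c(x = 0), fn)
  expect_equal(lap2$F, -0.5 * log(2), tolerance = 1e-6)

  # two data-free dimensions with different prior variances still give 0
  fn3 <- function(th) sum(dnorm(th, c(0, -2), c(1, 10), log = TRUE))
  lap3 <- laplace_evidence(c(a = 0, b = -2), fn3)
  expect_equal(lap3$F, 0, tolerance = 1e-5)
})

test_that("a free but irrelevant parameter never raises the evidence by more than its Occam cost", {
  sched <- make_task_schedule(task_config(seed = 70))
  gen <- advice_model("rw", "cue_only", "fixed")
  dat <- simulate_player(sched, gen, seed = 9)
  f_cue <- fit_advice_model(dat, gen)
  f_int <- fit_advice_model(dat, advice_model("rw", "integrated", "fixed"))
  # the integrated model nests the generator; extra dimensions cannot win
  # more evidence than the likelihood they explain
  expect_lt(f_int$evidence, f_cue$evidence + 3)
})
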