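test_that("logistic sigmoid has the expected values and symmetry", {
  expect_equal(logistic_sigmoid(0), 0.5)
  expect_equal(logistic_sigmoid(2), 1 / (1 + exp(-2)), tolerance = 1e-12)
  x <- seq(-20, 20, by = 0.5)
  expect_equal(logistic_sigmoid(x) + logistic_sigmoid(-x), rep(1, length(x)))
  expect_true(all(logistic_sigmoid(c(-30, 30)) > 0 &
                    logistic_sigmoid(c(-30, 30)) < 1))
})

test_that("a single HGF update matches the hand-computed step", {
  p <- hgf_params(kappa = 0.5, omega = -2, theta = 0.5,
                  mu2_0 = 0, sa2_0 = 1, mu3_0 = 1, sa3_0 = 1)
  st <- list(mu2 = 0, sa2 = 1, mu3 = 1, sa3 = 1)
  out <- hgf_step(st, 1, p)
  # frozen values from independent hand evaluation of the update equations
  expect_equal(out$mu2, 0.46835, tolerance = 1e-4)
  expect_equal(out$mu3, 0.99628, tolerance = 1e-4)
  expect_equal(1 / out$sa2, 1.06757, tolerance = 1e-4)
})

test_that("zero prediction error leaves the level-2 mean unchanged", {
  p <- hgf_params()
  st <- list(mu2 = 0, sa2 = 1, mu3 = 1, sa3 = 1)
  out <- hgf_step(st, 0.5, p)  # hypothetical continuous input u = muhat1
  expect_equal(out$mu2, 0)
})

test_that("vanishing coupling freezes level 3 and nests the reduced filter", {
  u <- reversal_inputs(60)
  p_small <- hgf_params(kappa = 1e-9)
  t3 <- filter_sequence(u, "hgf3", p_small)
  expect_equal(t3$mu3, rep(p_small$mu3_0, length(u)), tolerance = 1e-6)

  t2 <- filter_sequence(u, "hgf2", p_small)
  for (col in c("muhat1", "mu2", "sa2", "pihat2", "delta1"))
    expect_equal(t3[[col]], t2[[col]], tolerance = 1e-9)
  # the reduced filter never moves level 3 whatever the coupling
  t2b <- filter_sequence(u, "hgf2", hgf_params(kappa = 0.5))
  expect_equal(t2b$mu3, rep(1, length(u)))
  expect_equal(t2b$sa3, rep(1, length(u)))
})

test_that("Rescorla-Wagner updates are exact and have the fixed point", {
  expect_equal(rw_step(0.5, 1, 0.2), 0.6)
  expect_equal(rw_step(0.3, 1, 1), 1)
  expect_equal(rw_step(0.7, 0.7, 0.4), 0.7)
  set.seed(42)
  u <- rbinom(2000, 1, 0.65)
  traj <- filter_sequence(u, "rw", rw_params(alpha = 0.1))
  expect_lt(abs(mean(traj$v[1001:2000]) - 0.65), 0.02)
})

test_that("beliefs converge toward a stable input rate", {
  set.seed(9)
  u <- rbinom(1000, 1, 0.8)
  traj <- filter_sequence(u, "hgf2")
  expect_lt(abs(mean(traj$muhat1[501:1000]) - 0.8), 0.05)
})

test_that("empty input yields an empty trajectory", {
  traj <- filter_sequence(integer(0), "hgf3")
  expect_equal(nrow(traj), 0)
  traj_rw <- filter_sequence(integer(0), "rw")
  expect_equal(nrow(traj_rw), 0)
})

test_that("volatility estimates rise after a contingency reversal", {
  u <- reversal_inputs(120)
  traj <- filter_sequence(u, "hgf3")
  expect_gt(mean(traj$mu3[121:240]), mean(traj$mu3[1:120]))
})

test_that("the RW value over/undershoots around reversals relative to the HGF", {
  u <- reversal_inputs(120)
  hgf <- filter_sequence(u, "hgf3")
  rw <- filter_sequence(u, "rw", rw_params(alpha = 0.2))
  # the constant learning rate makes the RW value run both above and
  # below the generative rate more than the HGF's adaptive prediction:
  # larger mean absolute deviation across the volatile schedule, and more
  # jitter within the stable first phase
  rate <- rep(c(0.8, 0.2), each = 120)
  expect_gt(mean(abs(rw$vhat - rate)), mean(abs(hgf$muhat1 - rate)))
  stable <- 61:120
  expect_gt(sd(rw$vhat[stable]), sd(hgf$muhat1[stable]))
})

test_that("trajectory variances and precisions stay positive over random draws", {
  set.seed(1234)
  for (rep in 1:200) {
    p <- hgf_params(kappa = exp(rnorm(1, log(0.5), 0.5)),
                    omega = rnorm(1, -2, 1.5),
                    theta = plogis(rnorm(1, 0, 1)),
                    mu2_0 = rnorm(1), sa2_0 = exp(rnorm(1, 0, 0.5)),
                    mu3_0 = rnorm(1, 1, 1), sa3_0 = exp(rnorm(1, 0, 0.5)))
    u <- rbinom(60, 1, runif(1, 0.2, 0.8))
    traj <- tryCatch(filter_sequence(u, "hgf3", p),
                     hgf_rejection = function(e) NULL)
    if (is.null(traj)) next  # explicit rejection is the sanctioned exit
    expect_true(all(traj$sa2 > 0))
    expect_true(all(traj$sa3 > 0))
    expect_true(all(traj$pihat2 > 0))
    expect_true(all(traj$pihat3 > 0))
    expect_true(all(is.finite(traj$muhat1)))
    expect_true(all(traj$muhat1 >= 0 & traj$muhat1 <= 1))
  }
})

test_that("learning-rate diagnostics behave as precision ratios", {
  set.seed(77)
  u <- rbinom(99, 1, 0.8)
  traj <- filter_sequence(u, "hgf3")
  lr <- learning_rates(traj)
  # precision accumulates, so the early effective rate exceeds the late one
  expect_gt(mean(lr$lr1[1:10], na.rm = TRUE),
            mean(lr$lr1[70:99], na.rm = TRUE))

  # reversal spikes the first-level rate
  u2 <- reversal_inputs(120)
  lr2 <- learning_rates(filter_sequence(u2, "hgf3"))
  expect_gt(mean(lr2$lr1[121:140], na.rm = TRUE),
            mean(lr2$lr1[101:120], na.rm = TRUE))

  # vanishing coupling sends the third-level rate to zero
  lr3 <- learning_rates(filter_sequence(u, "hgf3", hgf_params(kappa = 1e-9)))
  expect_lt(max(abs(lr3$lr3)), 1e-8)
})

test_that("the variational filter tracks the exact grid filter", {
  u <- reversal_inputs(120)
  p <- hgf_params()
  oracle <- grid_filter_oracle(u, p)
  traj <- filter_sequence(u, "hgf3", p)
  expect_gt(cor(oracle, traj$muhat1), 0.9)
})
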