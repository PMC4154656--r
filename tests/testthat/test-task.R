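test_that("default schedule reproduces the design constants", {
  sched <- make_task_schedule(task_config(seed = 1))
  expect_equal(nrow(sched), 200)
  expect_equal(sum(!sched$is_rating), 192)
  expect_equal(sum(sched$is_rating), 8)
  counts <- table(sched$cue_p_blue[!sched$is_rating])
  expect_equal(length(counts), 6)
  expect_true(all(counts == 32))
})

test_that("schedules are deterministic given the seed", {
  a <- make_task_schedule(task_config(seed = 33))
  b <- make_task_schedule(task_config(seed = 33))
  expect_identical(a, b)
  c <- make_task_schedule(task_config(seed = 34))
  expect_false(identical(a$outcome_color, c$outcome_color))
})

test_that("configuration invariants are enforced", {
  expect_error(task_config(n_prediction_trials = 100), "divisible")
  expect_error(task_config(adviser_info_accuracy = 1), "strictly")
  expect_error(adviser_strategy(gold_range = c(50, 35)))
})

test_that("channel accuracies converge to their configured values", {
  cfg <- task_config(n_prediction_trials = 9996, n_rating_trials = 4,
                     seed = 7)
  sched <- make_task_schedule(cfg)
  acc <- mean(sched$private_info == sched$outcome_color)
  # 3-sigma binomial band around 0.8 at n = 10,000
  expect_lt(abs(acc - 0.8), 3 * sqrt(0.8 * 0.2 / nrow(sched)))

  ctl <- make_task_schedule(task_config(n_prediction_trials = 9996,
                                        n_rating_trials = 4,
                                        mode = "control", seed = 8))
  accs <- attr(ctl, "config")$control_deck_accuracies
  for (d in unique(ctl$deck)) {
    rows <- ctl$deck == d
    expect_lt(abs(mean(ctl$private_info[rows] == ctl$outcome_color[rows]) -
                    accs[d]),
              3 * sqrt(accs[d] * (1 - accs[d]) / sum(rows)) + 0.01)
  }
})

test_that("adviser strategies implement their rules", {
  cfg <- task_config(n_prediction_trials = 4998, n_rating_trials = 2,
                     seed = 5)
  sched <- make_task_schedule(cfg)

  helpful <- simulate_adviser(sched, adviser_strategy("helpful"))
  expect_identical(helpful, sched$private_info)
  acc <- mean(helpful == sched$outcome_color)
  expect_lt(abs(acc - 0.8), 3 * sqrt(0.8 * 0.2 / nrow(sched)))

  unif <- simulate_adviser(sched, adviser_strategy("uninformative"),
                           seed = 9)
  expect_lt(abs(mean(unif == sched$outcome_color) - 0.5),
            3 * sqrt(0.25 / nrow(sched)))

  # score pinned inside the gold range: deterministic misleading
  strat <- adviser_strategy("incentive_switching")
  scores <- rep(40, nrow(sched))
  adv <- simulate_adviser(sched, strat, scores = scores, seed = 2)
  expect_true(all(adv != sched$private_info))
  # outside both ranges: advice equals private information
  adv0 <- simulate_adviser(sched, strat, scores = rep(0, nrow(sched)),
                           seed = 2)
  expect_identical(adv0, sched$private_info)
  # missing score feedback is an error
  expect_error(simulate_adviser(sched, strat), "score")
})

test_that("simulated players respect score accounting and determinism", {
  sched <- make_task_schedule(task_config(seed = 21))
  mod <- advice_model("hgf3", "integrated", "volatility")
  dat <- simulate_player(sched, mod, seed = 4)
  dat2 <- simulate_player(sched, mod, seed = 4)
  expect_identical(dat$response_color, dat2$response_color)

  pred <- !dat$is_rating
  n_correct <- sum(dat$correct[pred])
  final <- dat$score[nrow(dat)]
  expect_equal(final, n_correct - (sum(pred) - n_correct))
  expect_true(all(is.na(dat$response_color[dat$is_rating])))
  expect_equal(sum(!is.na(dat$rating_value)), 8)
  expect_true(all(dat$rating_value[dat$is_rating] %in% c(0, 0.5, 1)))
})

test_that("cue-only players ignore the advice channel", {
  sched <- make_task_schedule(task_config(seed = 22))
  mod <- advice_model("hgf3", "cue_only", "fixed")
  dat <- simulate_player(sched, mod, seed = 6)
  inp <- advicehgf:::subject_inputs(dat)
  # P(follow) is driven by the cue probability of the advised colour only:
  # when the cue favours the advised colour the player follows, otherwise
  # defies (beta0 = 48 makes the rule near-deterministic)
  follows <- inp$y == 1
  expect_true(all(follows[inp$c > 0.6]))
  expect_true(all(!follows[inp$c < 0.4]))
})

test_that("an agent facing a helpful adviser outperforms one facing an uninformative adviser", {
  mod <- advice_model("hgf3", "integrated", "volatility")
  acc <- function(kind) {
    mean(vapply(1:20, function(i) {
      sched <- make_task_schedule(task_config(seed = 100 + i))
      dat <- simulate_player(sched, mod, strategy = adviser_strategy(kind),
                             seed = 200 + i)
      mean(dat$correct[!dat$is_rating])
    }, numeric(1)))
  }
  expect_gt(acc("helpful"), acc("uninformative"))
})

test_that("cohort mixes are validated and recorded", {
  expect_length(simulate_cohort(0), 0)
  expect_error(simulate_cohort(4, strategy_mix = c(helpful = 0.4)),
               "sum to 1")
  coh <- simulate_cohort(
    16,
    strategy_mix = c(helpful = 4, uninformative = 3,
                     incentive_switching = 9),
    model_mix = c(hgf3_vol_integrated = 1),
    seed = 12)
  expect_length(coh, 16)
  strategies <- vapply(coh, attr, "", "strategy")
  expect_equal(sum(strategies == "helpful"), 4)
  expect_equal(sum(strategies == "uninformative"), 3)
  expect_equal(sum(strategies == "incentive_switching"), 9)
  # probe positions shared across the cohort
  probes <- lapply(coh, function(d) d$trial[d$is_rating])
  expect_true(all(vapply(probes, identical, TRUE, probes[[1]])))
})

test_that("subject CSV round-trips and recomputes derived columns", {
  sched <- make_task_schedule(task_config(seed = 31))
  dat <- simulate_player(sched, advice_model("rw", "integrated"), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_subject_csv(dat, path)
  back <- read_subject_csv(path)
  expect_equal(back$u, dat$u)
  expect_equal(back$c, dat$c)
  expect_equal(back$y, dat$y)
  expect_equal(back$score, dat$score)
  # u is 1 exactly when advice matches outcome; c flips with advice colour
  pred <- !back$is_rating
  expect_equal(back$u[pred],
               as.integer(back$advice_color[pred] ==
                            back$outcome_color[pred]))
  blue <- pred & back$advice_color == "blue"
  expect_equal(back$c[blue], back$cue_p_blue[blue])
  green <- pred & back$advice_color == "green"
  expect_equal(back$c[green], 1 - back$cue_p_blue[green])
})
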