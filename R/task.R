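#' Task configuration
#'
#' Design constants of the adviser-player game. The main task has 192
#' prediction trials (plus 8 rating probes) with six balanced cue types
#' and an adviser whose private information predicts the outcome with a
#' constant 80% accuracy. In the control variant a blindfolded adviser
#' draws cards from six decks whose predictive accuracy is either 80% or
#' 20%, switching decks in blocks.
#'
#' @param n_prediction_trials Number of prediction trials (must be
#'   divisible by the number of cue types).
#' @param n_rating_trials Number of rating probes interleaved with the
#'   prediction trials.
#' @param cue_set Blue-win probabilities of the pie-chart cues.
#' @param adviser_info_accuracy Probability that the adviser's private
#'   information matches the drawn outcome (main task).
#' @param mode `"main"` or `"control"`.
#' @param control_deck_accuracies Predictive accuracies of the control
#'   task's card decks.
#' @param control_block_range Block lengths (trials) between deck switches
#'   are drawn uniformly from this range.
#' @param seed Integer seed; all schedule randomness flows from it.
#' @return A list of class `task_config`.
#' @export
task_config <- function(n_prediction_trials = 192,
                        n_rating_trials = 8,
                        cue_set = c(0.75, 0.65, 0.55, 0.45, 0.35, 0.25),
                        adviser_info_accuracy = 0.80,
                        mode = c("main", "control"),
                        control_deck_accuracies = rep(c(0.80, 0.20), each = 3),
                        control_block_range = c(20, 40),
                        seed = 1L) {
  mode <- match.arg(mode)
  if (n_prediction_trials %% length(cue_set) != 0)
    stop("n_prediction_trials must be divisible by the number of cue types")
  probs <- c(cue_set, adviser_info_accuracy, control_deck_accuracies)
  if (any(probs <= 0 | probs >= 1))
    stop("all probabilities must lie strictly in (0, 1)")
  structure(list(n_prediction_trials = n_prediction_trials,
                 n_rating_trials = n_rating_trials,
                 cue_set = cue_set,
                 adviser_info_accuracy = adviser_info_accuracy,
                 mode = mode,
                 control_deck_accuracies = control_deck_accuracies,
                 control_block_range = control_block_range,
                 seed = as.integer(seed)),
            class = "task_config")
}

#' Adviser strategy
#'
#' Strategies observed in the game: consistently `helpful` advisers pass
#' on their private information; `uninformative` advisers give advice that
#' matches the outcome only at chance; `incentive_switching` advisers pass
#' on their private information except while the player's score sits
#' inside one of the adviser's own reward ranges (gold 35-50, silver
#' 95-110), where they advise the opposite colour with probability
#' `mislead_prob`.
#'
#' @param kind Strategy kind.
#' @param gold_range,silver_range Score intervals in which the
#'   incentive-switching adviser profits from confining the player.
#' @param mislead_prob Probability of inverting the private information
#'   while the score is inside a reward range.
#' @param uninformative_accuracy Long-run advice-outcome match rate of the
#'   uninformative strategy.
#' @return A list of class `adviser_strategy`.
#' @export
adviser_strategy <- function(kind = c("helpful", "uninformative",
                                      "incentive_switching"),
                             gold_range = c(35, 50),
                             silver_range = c(95, 110),
                             mislead_prob = 1,
                             uninformative_accuracy = 0.5) {
  kind <- match.arg(kind)
  stopifnot(length(gold_range) == 2, length(silver_range) == 2,
            gold_range[1] <= gold_range[2],
            silver_range[1] <= silver_range[2],
            gold_range[2] < silver_range[1],
            mislead_prob >= 0, mislead_prob <= 1,
            uninformative_accuracy >= 0, uninformative_accuracy <= 1)
  structure(list(kind = kind, gold_range = gold_range,
                 silver_range = silver_range, mislead_prob = mislead_prob,
                 uninformative_accuracy = uninformative_accuracy),
            class = "adviser_strategy")
}

other_color <- function(color) ifelse(color == "blue", "green", "blue")

#' Generate a task schedule
#'
#' Draws the per-trial cue probabilities (balanced over the cue set on the
#' prediction trials), outcomes, adviser private information (main task)
#' or deck assignment and drawn card (control task), and the positions of
#' the rating probes. Fully deterministic given the seed in `config`.
#'
#' @param config A [task_config()].
#' @param probe_positions Optional integer vector of probe trial indices,
#'   e.g. to share probe timing across a cohort; drawn from the schedule
#'   seed when `NULL`.
#' @return Data frame of class `task_schedule` with columns `trial`,
#'   `is_rating`, `cue_p_blue`, `outcome_color`, `private_info` and (in
#'   control mode) `deck`. `private_info` is the card colour in control
#'   mode.
#' @export
make_task_schedule <- function(config = task_config(),
                               probe_positions = NULL) {
  set.seed(config$seed)
  n_pred <- config$n_prediction_trials
  n_probe <- config$n_rating_trials
  n <- n_pred + n_probe

  if (is.null(probe_positions)) {
    probe_positions <- sort(sample.int(n, n_probe))
  } else {
    stopifnot(length(probe_positions) == n_probe,
              all(probe_positions >= 1 & probe_positions <= n))
    probe_positions <- sort(as.integer(probe_positions))
  }
  is_rating <- seq_len(n) %in% probe_positions

  cue <- numeric(n)
  cue[!is_rating] <- sample(rep(config$cue_set, n_pred / length(config$cue_set)))
  cue[is_rating] <- sample(config$cue_set, n_probe, replace = TRUE)

  outcome <- ifelse(stats::runif(n) < cue, "blue", "green")

  out <- data.frame(trial = seq_len(n), is_rating = is_rating,
                    cue_p_blue = cue, outcome_color = outcome,
                    stringsAsFactors = FALSE)

  if (config$mode == "main") {
    match_info <- stats::runif(n) < config$adviser_info_accuracy
    out$private_info <- ifelse(match_info, outcome, other_color(outcome))
  } else {
    n_decks <- length(config$control_deck_accuracies)
    deck <- integer(0)
    cur <- sample.int(n_decks, 1)
    while (length(deck) < n) {
      len <- sample(seq(config$control_block_range[1],
                        config$control_block_range[2]), 1)
      deck <- c(deck, rep(cur, len))
      nxt <- sample.int(n_decks - 1, 1)
      cur <- setdiff(seq_len(n_decks), cur)[nxt]
    }
    out$deck <- deck[seq_len(n)]
    acc <- config$control_deck_accuracies[out$deck]
    match_card <- stats::runif(n) < acc
    out$private_info <- ifelse(match_card, outcome, other_color(outcome))
  }

  attr(out, "config") <- config
  class(out) <- c("task_schedule", "data.frame")
  out
}

in_ranges <- function(score, strategy) {
  (score >= strategy$gold_range[1] & score <= strategy$gold_range[2]) |
    (score >= strategy$silver_range[1] & score <= strategy$silver_range[2])
}

# Advice on a single trial given the adviser's current view of the game.
advise_trial <- function(strategy, private_info, outcome, score) {
  switch(strategy$kind,
    helpful = private_info,
    uninformative = {
      if (stats::runif(1) < strategy$uninformative_accuracy) outcome
      else other_color(outcome)
    },
    incentive_switching = {
      if (in_ranges(score, strategy) &&
          stats::runif(1) < strategy$mislead_prob)
        other_color(private_info)
      else private_info
    })
}

#' Simulate an adviser's advice sequence
#'
#' For the static strategies the advice depends only on the schedule:
#' helpful advisers always pass on their private information;
#' uninformative advisers match the outcome at their configured chance
#' rate. The incentive-switching strategy conditions on the player's
#' running score, so a per-trial score sequence (score *before* each
#' trial) must be supplied; in a live game use [simulate_player()], which
#' closes the loop. In control mode the blindfolded adviser simply shows
#' the drawn card.
#'
#' @param schedule A [make_task_schedule()] result.
#' @param strategy An [adviser_strategy()].
#' @param scores Numeric vector of pre-trial player scores (required for
#'   `incentive_switching`).
#' @param seed Integer seed for the stochastic strategies.
#' @return Character vector of advised colours, one per trial.
#' @export
simulate_adviser <- function(schedule, strategy = adviser_strategy(),
                             scores = NULL, seed = 1L) {
  config <- attr(schedule, "config")
  if (!is.null(config) && config$mode == "control")
    return(schedule$private_info)
  if (strategy$kind == "incentive_switching") {
    if (is.null(scores))
      stop("incentive_switching requires the player's score sequence; ",
           "supply `scores` or simulate a closed loop via simulate_player()")
    stopifnot(length(scores) == nrow(schedule))
  }
  set.seed(seed)
  vapply(seq_len(nrow(schedule)), function(k) {
    advise_trial(strategy, schedule$private_info[k],
                 schedule$outcome_color[k],
                 if (is.null(scores)) 0 else scores[k])
  }, character(1))
}

# Discretize a reliability estimate into the rating code
# {misleading = 0, uninformative = 0.5, helpful = 1} by thirds.
discretize_rating <- function(m, noise_sd = 0) {
  if (noise_sd > 0) m <- pmin(pmax(m + stats::rnorm(length(m), 0, noise_sd),
                                   0), 1)
  ifelse(m < 1 / 3, 0, ifelse(m < 2 / 3, 0.5, 1))
}

#' Simulate a player interacting with an adviser
#'
#' Runs the full closed loop for one subject: on every prediction trial
#' the adviser issues advice (conditioning on the current score for the
#' incentive-switching strategy), the player forms the integrated belief
#' under `model`, samples a follow/defy response from the choice rule
#' (optionally contaminated by a lapse probability `xi`), and the score
#' and the perceptual filter are updated with the realized advice
#' accuracy. On rating probes the player reports the current reliability
#' estimate discretized to \{0, 0.5, 1\} and neither responds nor updates.
#'
#' @param schedule A [make_task_schedule()] result.
#' @param model An [advice_model()].
#' @param params Named list of native parameters; defaults to the prior
#'   means of `model`.
#' @param strategy An [adviser_strategy()] (ignored in control mode).
#' @param xi Lapse probability used when sampling responses
#'   (see [noisy_choice_probability()]).
#' @param rating_noise Gaussian noise added to the reliability estimate
#'   before discretizing ratings.
#' @param seed Integer seed.
#' @return Data frame of class `advice_subject` with per-trial columns
#'   `trial`, `is_rating`, `cue_p_blue`, `advice_color`, `outcome_color`,
#'   `response_color`, `rating_value` and the derived `u`, `c`, `y`,
#'   `correct`, `score`. Ground truth (model, parameters, strategy, seed)
#'   is kept in attributes.
#' @export
simulate_player <- function(schedule, model, params = NULL,
                            strategy = adviser_strategy("incentive_switching"),
                            xi = 0, rating_noise = 0, seed = 1L) {
  config <- attr(schedule, "config")
  if (is.null(params)) params <- prior_mean_params(model)
  check_native_params(model, params)
  set.seed(seed)

  n <- nrow(schedule)
  control <- !is.null(config) && config$mode == "control"
  use_rw <- model$perceptual == "rw"
  freeze3 <- model$perceptual == "hgf2"
  if (use_rw) {
    v <- params$v_0
  } else {
    state <- list(mu2 = params$mu2_0, sa2 = params$sa2_0,
                  mu3 = params$mu3_0, sa3 = params$sa3_0)
  }
  zeta <- switch(model$info, integrated = params$zeta,
                 advice_only = 1, cue_only = 0)

  advice <- response <- rep(NA_character_, n)
  rating <- rep(NA_real_, n)
  score <- 0L
  score_track <- integer(n)

  for (k in seq_len(n)) {
    m_now <- if (use_rw) v else logistic_sigmoid(state$mu2)
    if (schedule$is_rating[k]) {
      rating[k] <- discretize_rating(m_now, rating_noise)
      score_track[k] <- score
      next
    }
    adv <- if (control) schedule$private_info[k]
           else advise_trial(strategy, schedule$private_info[k],
                             schedule$outcome_color[k], score)
    advice[k] <- adv
    c_k <- if (adv == "blue") schedule$cue_p_blue[k]
           else 1 - schedule$cue_p_blue[k]
    b <- integrated_belief(m_now, c_k, zeta)
    beta <- if (model$noise == "volatility")
      params$beta0 * exp(-state$mu3) else params$beta0
    p <- noisy_choice_probability(choice_probability(b, beta), xi)
    y <- stats::runif(1) < p
    response[k] <- if (y) adv else other_color(adv)
    correct <- response[k] == schedule$outcome_color[k]
    score <- score + if (correct) 1L else -1L
    score_track[k] <- score
    u <- as.integer(adv == schedule$outcome_color[k])
    if (use_rw) v <- rw_step(v, u, params$alpha)
    else state <- hgf_step(state, u, params, freeze3 = freeze3)
  }

  out <- data.frame(trial = schedule$trial, is_rating = schedule$is_rating,
                    cue_p_blue = schedule$cue_p_blue,
                    advice_color = advice,
                    outcome_color = schedule$outcome_color,
                    response_color = response, rating_value = rating,
                    stringsAsFactors = FALSE)
  out <- as_advice_subject(out)
  attr(out, "model") <- model$label
  attr(out, "params") <- params
  attr(out, "strategy") <- if (control) "control" else strategy$kind
  attr(out, "xi") <- xi
  attr(out, "seed") <- as.integer(seed)
  attr(out, "config") <- config
  out
}

#' Derive modeling inputs on a raw subject table
#'
#' Adds the derived per-trial quantities used by the models: advice
#' accuracy `u` (1 if the advice matched the outcome), the cue probability
#' `c` of the advised colour, the follow/defy response `y` (1 if the
#' chosen colour matched the advice; `NA` for missed responses), the
#' `correct` flag and the running `score` (+1 for a correct prediction,
#' -1 for an incorrect or missed one; rating probes leave it unchanged).
#'
#' @param data Data frame with the raw columns `trial`, `is_rating`,
#'   `cue_p_blue`, `advice_color`, `outcome_color`, `response_color`,
#'   `rating_value`.
#' @return The same data frame of class `advice_subject` with derived
#'   columns appended.
#' @export
as_advice_subject <- function(data) {
  needed <- c("trial", "is_rating", "cue_p_blue", "advice_color",
              "outcome_color", "response_color", "rating_value")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  data$u <- ifelse(is.na(data$advice_color), NA_integer_,
                   as.integer(data$advice_color == data$outcome_color))
  data$c <- ifelse(is.na(data$advice_color), NA_real_,
                   ifelse(data$advice_color == "blue",
                          data$cue_p_blue, 1 - data$cue_p_blue))
  data$y <- ifelse(is.na(data$response_color) | is.na(data$advice_color),
                   NA_integer_,
                   as.integer(data$response_color == data$advice_color))
  data$correct <- ifelse(is.na(data$response_color), NA,
                         data$response_color == data$outcome_color)
  delta <- ifelse(data$is_rating, 0L,
                  ifelse(!is.na(data$correct) & data$correct, 1L, -1L))
  data$score <- cumsum(delta)
  class(data) <- unique(c("advice_subject", class(data)))
  data
}

# Modeled trials only: prediction trials that carry advice.
subject_inputs <- function(data) {
  keep <- !data$is_rating & !is.na(data$advice_color)
  list(u = data$u[keep], c = data$c[keep], y = data$y[keep],
       trial = data$trial[keep])
}

#' Simulate a cohort of subjects
#'
#' Generates independent seeded subjects with adviser strategies and
#' generating models drawn according to the requested mixes. Probe
#' positions are drawn once from the cohort seed and shared across
#' subjects, mirroring the probes being presented at the same times for
#' everyone.
#'
#' @param n_subjects Number of subjects.
#' @param strategy_mix Named numeric vector of strategy proportions
#'   (names among `helpful`, `uninformative`, `incentive_switching`);
#'   must sum to 1. Counts summing to `n_subjects` are also accepted.
#' @param model_mix Named numeric vector of proportions over model labels
#'   from [model_space()]; must sum to 1 (or counts summing to
#'   `n_subjects`).
#' @param params Optional named list of parameter lists per model label;
#'   prior means are used where absent.
#' @param xi Lapse probability for response sampling.
#' @param config Base [task_config()]; each subject gets a distinct
#'   schedule seed derived from `seed`.
#' @param seed Cohort seed.
#' @return List of `advice_subject` data frames.
#' @export
simulate_cohort <- function(n_subjects,
                            strategy_mix = c(incentive_switching = 1),
                            model_mix = c(hgf3_vol_integrated = 1),
                            params = NULL, xi = 0,
                            config = task_config(), seed = 1L) {
  if (n_subjects == 0) return(list())
  expand_mix <- function(mix, what) {
    tot <- sum(mix)
    if (isTRUE(all.equal(tot, 1))) counts <- round(mix * n_subjects)
    else if (isTRUE(all.equal(tot, n_subjects))) counts <- mix
    else stop(what, " must sum to 1 (proportions) or to n_subjects (counts)")
    if (sum(counts) != n_subjects)
      counts[1] <- counts[1] + n_subjects - sum(counts)
    rep(names(mix), counts)
  }
  strategies <- expand_mix(strategy_mix, "strategy_mix")
  models <- expand_mix(model_mix, "model_mix")
  space <- model_space()
  bad <- setdiff(unique(models), names(space))
  if (length(bad)) stop("unknown model labels: ", paste(bad, collapse = ", "))

  set.seed(seed)
  n_total <- config$n_prediction_trials + config$n_rating_trials
  probes <- sort(sample.int(n_total, config$n_rating_trials))
  subj_seeds <- sample.int(.Machine$integer.max %/% 2, n_subjects)

  lapply(seq_len(n_subjects), function(i) {
    cfg <- config
    cfg$seed <- subj_seeds[i]
    sched <- make_task_schedule(cfg, probe_positions = probes)
    mod <- space[[models[i]]]
    pp <- if (!is.null(params) && !is.null(params[[models[i]]]))
      params[[models[i]]] else NULL
    simulate_player(sched, mod, params = pp,
                    strategy = adviser_strategy(strategies[i]),
                    xi = xi, seed = subj_seeds[i] + 1L)
  })
}

#' Write / read a subject table as CSV
#'
#' The on-disk format carries only the raw columns (`trial`, `cue_p_blue`,
#' `advice_color`, `outcome_color`, `response_color`, `is_rating`,
#' `rating_value`, colours coded `blue`/`green`); derived quantities are
#' recomputed on read by [as_advice_subject()].
#'
#' @param data An `advice_subject` data frame.
#' @param path File path.
#' @return `read_subject_csv()` returns an `advice_subject` data frame.
#' @export
write_subject_csv <- function(data, path) {
  raw <- data[, c("trial", "cue_p_blue", "advice_color", "outcome_color",
                  "response_color", "is_rating", "rating_value")]
  utils::write.csv(raw, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_csv
#' @export
read_subject_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$advice_color[raw$advice_color %in% c("", "NA")] <- NA_character_
  raw$response_color[raw$response_color %in% c("", "NA")] <- NA_character_
  as_advice_subject(raw)
}
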