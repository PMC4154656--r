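## Simulation study and end-to-end cohort pipeline: generate, fit the
## model space, run BMS, and summarize recovery and rating validity.

#' Evidence matrix for a cohort
#'
#' Fits every model in `models` to every subject and collects the Laplace
#' log evidences into an N x K matrix (the hand-off to [run_bms_report()]).
#'
#' @param cohort List of `advice_subject` data frames.
#' @param models Named list of [advice_model()]s; default the full
#'   12-model space.
#' @param n_starts,seed Passed to [fit_advice_model()].
#' @param keep_fits Also return the fit objects.
#' @return List with `F` (evidence matrix), `failures` (data frame of
#'   failed subject x model cells, if any) and optionally `fits`.
#' @export
evidence_matrix <- function(cohort, models = model_space(),
                            n_starts = 1, seed = 1L, keep_fits = FALSE) {
  N <- length(cohort)
  K <- length(models)
  F <- matrix(NA_real_, N, K, dimnames = list(NULL, names(models)))
  fits <- if (keep_fits) vector("list", N)
  failures <- list()
  for (i in seq_len(N)) {
    if (keep_fits) fits[[i]] <- list()
    for (j in seq_len(K)) {
      fit <- fit_advice_model(cohort[[i]], models[[j]],
                              n_starts = n_starts,
                              seed = seed + 1000L * i + j)
      if (isTRUE(fit$failed)) {
        failures[[length(failures) + 1]] <-
          data.frame(subject = i, model = names(models)[j])
      } else {
        F[i, j] <- fit$evidence
      }
      if (keep_fits) fits[[i]][[names(models)[j]]] <- fit
    }
  }
  out <- list(F = F,
              failures = if (length(failures)) do.call(rbind, failures)
                         else NULL)
  if (keep_fits) out$fits <- fits
  out
}

#' Model recovery study
#'
#' Generates `datasets_per_model` synthetic subjects from each of the four
#' perceptual/noise generators under the integrated response model, using
#' the prior means as parameter values and lapse-contaminated responses
#' (`xi`), then refits the same four candidate models to every dataset.
#' The winner of each dataset is the candidate with the highest log
#' evidence; per-generator group BMS results are reported secondarily.
#'
#' @param datasets_per_model Datasets per generating model.
#' @param xi Lapse probability applied when generating responses.
#' @param generators Named list of generating/candidate models; default
#'   the four integrated-information models.
#' @param strategy Adviser strategy faced by the simulated players.
#' @param config Base [task_config()].
#' @param n_starts Optimizer starts per fit.
#' @param seed Master seed.
#' @return Object of class `advice_recovery`: list with `confusion`
#'   (row-stochastic matrix, rows = generator, columns = selected model),
#'   `evidence` (list of per-generator evidence matrices), `group_bms`
#'   (per-generator pooled BMS), `failures`.
#' @export
run_model_recovery <- function(datasets_per_model = 20, xi = 0.1,
                               generators = integrated_generators(),
                               strategy = adviser_strategy("incentive_switching"),
                               config = task_config(),
                               n_starts = 1, seed = 1L) {
  stopifnot(datasets_per_model >= 1)
  G <- length(generators)
  confusion <- matrix(0, G, G,
                      dimnames = list(generated = names(generators),
                                      selected = names(generators)))
  evidence <- list()
  group_bms <- list()
  failures <- NULL
  set.seed(seed)
  sched_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                   G * datasets_per_model),
                        G, datasets_per_model)
  for (g in seq_len(G)) {
    cohort <- lapply(seq_len(datasets_per_model), function(d) {
      cfg <- config
      cfg$seed <- sched_seeds[g, d]
      sched <- make_task_schedule(cfg)
      simulate_player(sched, generators[[g]], xi = xi,
                      strategy = strategy, seed = sched_seeds[g, d] + 1L)
    })
    em <- evidence_matrix(cohort, generators, n_starts = n_starts,
                          seed = seed + g)
    evidence[[names(generators)[g]]] <- em$F
    if (!is.null(em$failures)) failures <- rbind(failures, em$failures)
    ok <- stats::complete.cases(em$F)
    winners <- apply(em$F[ok, , drop = FALSE], 1, which.max)
    confusion[g, ] <- tabulate(winners, G) / sum(ok)
    group_bms[[names(generators)[g]]] <-
      bms(em$F[ok, , drop = FALSE], seed = seed + g)
  }
  structure(list(confusion = confusion, evidence = evidence,
                 group_bms = group_bms, failures = failures,
                 datasets_per_model = datasets_per_model, xi = xi,
                 seed = seed),
            class = "advice_recovery")
}

#' The four integrated-information generators
#'
#' The perceptual/noise combinations crossed with the integrated response
#' model, used for the model recovery study.
#'
#' @return Named list of four [advice_model()]s.
#' @export
integrated_generators <- function() {
  mods <- list(advice_model("hgf3", "integrated", "volatility"),
               advice_model("hgf3", "integrated", "fixed"),
               advice_model("hgf2", "integrated", "fixed"),
               advice_model("rw", "integrated", "fixed"))
  stats::setNames(mods, vapply(mods, `[[`, "", "label"))
}

#' @export
print.advice_recovery <- function(x, digits = 2, ...) {
  cat("<advice_recovery> ", x$datasets_per_model,
      " datasets per generator, lapse xi = ", x$xi, "\n", sep = "")
  cat("Confusion matrix (rows = generating model, ",
      "cols = selected by evidence):\n", sep = "")
  print(round(x$confusion, digits))
  invisible(x)
}

#' Plot a model-recovery confusion matrix
#'
#' @param x An `advice_recovery`.
#' @param ... Ignored.
#' @export
plot.advice_recovery <- function(x, ...) {
  cm <- x$confusion
  G <- nrow(cm)
  graphics::image(seq_len(G), seq_len(G), t(cm[G:1, ]),
                  col = grDevices::grey.colors(32, start = 1, end = 0.2),
                  axes = FALSE, xlab = "selected", ylab = "generated",
                  zlim = c(0, 1))
  graphics::axis(1, seq_len(G), colnames(cm), cex.axis = 0.7)
  graphics::axis(2, seq_len(G), rev(rownames(cm)), cex.axis = 0.7, las = 1)
  for (i in seq_len(G)) for (j in seq_len(G))
    graphics::text(j, G + 1 - i, sprintf("%.2f", cm[i, j]),
                   col = if (cm[i, j] > 0.5) "white" else "black")
  invisible(x)
}

#' End-to-end cohort analysis pipeline
#'
#' Fits the full model space to every subject, assembles the evidence
#' matrix, runs model- and family-level random-effects BMS, and
#' summarizes the MAP parameter estimates (native-space mean and SD
#' across subjects) under the model with the highest exceedance
#' probability.
#'
#' @param cohort List of `advice_subject` data frames.
#' @param models Candidate models; default the full 12-model space.
#' @param partitions Family partitions for [run_bms_report()].
#' @param n_starts,seed Fitting settings.
#' @return Object of class `advice_report`: list with `F`, `bms`
#'   (an `advice_bms_report`), `winner` (label), `parameter_summary`
#'   (mean/SD of MAP estimates under the winner), `fits`, `failures`.
#' @export
run_cohort_pipeline <- function(cohort, models = model_space(),
                                partitions = default_partitions(),
                                n_starts = 1, seed = 1L) {
  em <- evidence_matrix(cohort, models, n_starts = n_starts, seed = seed,
                        keep_fits = TRUE)
  report <- run_bms_report(em$F, partitions = partitions, seed = seed)
  winner <- names(which.max(report$model$xp))
  est <- do.call(rbind, lapply(em$fits, function(fl) coef(fl[[winner]])))
  parameter_summary <- data.frame(parameter = colnames(est),
                                  mean = colMeans(est),
                                  sd = apply(est, 2, stats::sd),
                                  row.names = NULL)
  structure(list(F = em$F, bms = report, winner = winner,
                 parameter_summary = parameter_summary,
                 fits = em$fits, failures = em$failures, seed = seed),
            class = "advice_report")
}

#' @export
print.advice_report <- function(x, digits = 4, ...) {
  cat("<advice_report> N =", nrow(x$F), "subjects,", ncol(x$F), "models\n")
  cat("Winning model (highest exceedance):", x$winner, "\n\n")
  print(x$bms, digits = digits)
  cat("\nMAP parameter summary under", x$winner, "(native space):\n")
  print(transform(x$parameter_summary, mean = round(mean, digits),
                  sd = round(sd, digits)))
  invisible(x)
}

#' Validate belief trajectories against explicit ratings
#'
#' Regresses each subject's coded ratings (helpful = 1, uninformative =
#' 0.5, misleading = 0) on the model's predicted advice reliability at
#' the probe trials (first-level OLS), then tests the per-subject slopes
#' against zero with a one-sample t-test (second-level random-effects
#' analysis). Subjects with fewer than two probes or a zero-variance
#' regressor are skipped with a warning.
#'
#' @param cohort List of `advice_subject` data frames with rating probes.
#' @param model Perceptual/response model used to form the reliability
#'   predictions; defaults to the three-level HGF.
#' @param params Parameter list or a list of per-subject parameter lists;
#'   prior means when `NULL`.
#' @return Object of class `rating_validation`: list with `betas`
#'   (per-subject slopes), `t_test` (the second-level test), `skipped`.
#' @export
validate_ratings <- function(cohort,
                             model = advice_model("hgf3", "integrated",
                                                  "volatility"),
                             params = NULL) {
  per_subject <- !is.null(params) && is.list(params) &&
    !is.null(params[[1]]) && is.list(params[[1]])
  betas <- numeric(0)
  skipped <- integer(0)
  for (i in seq_along(cohort)) {
    data <- cohort[[i]]
    pp <- if (per_subject) params[[i]] else params
    if (is.null(pp)) pp <- prior_mean_params(model)
    m_probe <- reliability_at_probes(data, model, pp)
    ratings <- data$rating_value[data$is_rating]
    keep <- !is.na(ratings) & !is.na(m_probe)
    if (sum(keep) < 2 || stats::sd(m_probe[keep]) == 0) {
      skipped <- c(skipped, i)
      next
    }
    betas <- c(betas, unname(stats::coef(
      stats::lm(ratings[keep] ~ m_probe[keep]))[2]))
  }
  if (length(skipped))
    warning("skipped subjects with <2 usable probes or a constant ",
            "regressor: ", paste(skipped, collapse = ", "))
  if (length(betas) < 2)
    stop("fewer than two subjects with usable rating probes")
  structure(list(betas = betas, t_test = stats::t.test(betas),
                 skipped = skipped),
            class = "rating_validation")
}

# Predicted advice reliability carried into each probe trial: the belief
# state after the most recent modeled prediction trial.
reliability_at_probes <- function(data, model, params) {
  inp <- subject_inputs(data)
  traj <- filter_sequence(inp$u, model$perceptual,
                          params[intersect(names(params),
                                           c("kappa", "omega", "theta",
                                             "mu2_0", "sa2_0", "mu3_0",
                                             "sa3_0", "alpha", "v_0"))])
  m <- predicted_advice_reliability(traj)
  ## posterior after trial k = prediction for trial k+1; prepend the prior
  post <- c(m, if (identical(attr(traj, "perceptual"), "rw"))
    traj$v[length(traj$v)] else logistic_sigmoid(utils::tail(traj$mu2, 1)))
  probe_trials <- data$trial[data$is_rating]
  vapply(probe_trials, function(t) {
    n_before <- sum(inp$trial < t)
    post[n_before + 1]
  }, numeric(1))
}

#' @export
print.rating_validation <- function(x, ...) {
  cat("<rating_validation> N =", length(x$betas), "subjects\n")
  cat("mean slope:", format(mean(x$betas), digits = 4),
      "  t =", format(unname(x$t_test$statistic), digits = 4),
      "  p =", format(x$t_test$p.value, digits = 3), "\n")
  invisible(x)
}
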