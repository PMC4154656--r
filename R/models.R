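#' Specify one cell of the factorial model space
#'
#' A model couples a perceptual (belief-updating) variant with a response
#' model. The response model is described by two factors: which
#' information sources enter the integrated belief (`info`) and whether
#' the decision noise is fixed or coupled to the predicted adviser
#' volatility (`noise`). Volatility-coupled noise is only defined for the
#' three-level HGF, whose level-3 state it reads.
#'
#' @param perceptual `"hgf3"`, `"hgf2"` (no-volatility HGF) or `"rw"`.
#' @param info `"integrated"`, `"advice_only"` or `"cue_only"`.
#' @param noise `"fixed"` or `"volatility"`.
#' @return An object of class `advice_model`: a list with the three
#'   factors and a `label`.
#' @export
#' @examples
#' advice_model("hgf3", "integrated", "volatility")  # the winning model
advice_model <- function(perceptual = c("hgf3", "hgf2", "rw"),
                         info = c("integrated", "advice_only", "cue_only"),
                         noise = c("fixed", "volatility")) {
  perceptual <- match.arg(perceptual)
  info <- match.arg(info)
  noise <- match.arg(noise)
  if (noise == "volatility" && perceptual != "hgf3")
    stop("volatility-coupled decision noise is only valid with the ",
         "three-level HGF")
  structure(list(perceptual = perceptual, info = info, noise = noise,
                 label = paste(perceptual,
                               if (noise == "volatility") "vol" else "fix",
                               sub("_only", "", info), sep = "_")),
            class = "advice_model")
}

#' @export
print.advice_model <- function(x, ...) {
  cat("<advice_model> ", x$label, "\n", sep = "")
  cat("  perceptual: ", x$perceptual, "\n  information: ", x$info,
      "\n  decision noise: ", x$noise, "\n", sep = "")
  invisible(x)
}

#' The 12-model factorial space
#'
#' Four perceptual/noise combinations (three-level HGF with
#' volatility-coupled noise, three-level HGF with fixed noise,
#' no-volatility HGF, Rescorla-Wagner) crossed with three information
#' models (integrated, advice-only, cue-only).
#'
#' @return Named list of 12 [advice_model()] objects, in the column-major
#'   order of the four perceptual/noise combinations.
#' @export
model_space <- function() {
  cells <- list(c("hgf3", "volatility"), c("hgf3", "fixed"),
                c("hgf2", "fixed"), c("rw", "fixed"))
  infos <- c("integrated", "advice_only", "cue_only")
  out <- list()
  for (cell in cells)
    for (info in infos) {
      mod <- advice_model(cell[1], info, cell[2])
      out[[mod$label]] <- mod
    }
  out
}

#' Standard model-space partitions for family-level inference
#'
#' Three partitions of the 12-model space: by perceptual/noise combination
#' (4 families), by information model (3 families), and the 2-way
#' volatility-coupled versus fixed decision-noise split.
#'
#' @return Named list of partitions; each partition is a named list of
#'   model-label vectors.
#' @export
default_partitions <- function() {
  labs <- names(model_space())
  list(
    perceptual = list(
      hgf_volatility = grep("^hgf3_vol", labs, value = TRUE),
      hgf_decision_noise = grep("^hgf3_fix", labs, value = TRUE),
      no_volatility_hgf = grep("^hgf2_fix", labs, value = TRUE),
      rescorla_wagner = grep("^rw_fix", labs, value = TRUE)),
    information = list(
      integrated = grep("integrated$", labs, value = TRUE),
      advice_only = grep("advice$", labs, value = TRUE),
      cue_only = grep("cue$", labs, value = TRUE)),
    noise = list(
      volatility = grep("^hgf3_vol", labs, value = TRUE),
      decision_noise = grep("_fix_", labs, value = TRUE)))
}

#' Prior specification for a model
#'
#' One row per parameter: the native-space prior mean, the prior variance
#' in the estimation space, the transform linking the two
#' (`identity`, `log`, or `logit`), and whether the parameter is fixed
#' (zero prior variance; excluded from optimization). Defaults encode the
#' relatively uninformative priors of the study: for the three-level HGF,
#' kappa 0.5 (log space, var 1), omega -2 (var 100), theta 0.5 (logit
#' space, var 1), initial beliefs mu2_0 = 0, sa2_0 = 1, mu3_0 = 1,
#' sa3_0 = 1 (var 1 each); the no-volatility variant fixes kappa, theta,
#' mu3_0 and sa3_0; Rescorla-Wagner has alpha 0.2 and v_0 0.5 (logit
#' space, var 1); the response model has zeta 0.5 (logit space, var 1;
#' structurally fixed at 1 or 0 in the reduced models) and beta0 48 (log
#' space, var 1).
#'
#' Cue-only models with fixed decision noise have a likelihood that does
#' not depend on the perceptual parameters; these are marked fixed so the
#' model contributes only its `beta0` dimension to the evidence.
#'
#' @param model An [advice_model()].
#' @return Data frame of class `prior_spec` with columns `parameter`,
#'   `transform`, `mean_native`, `var_est`, `fixed`.
#' @export
default_priors <- function(model) {
  row <- function(parameter, transform, mean_native, var_est)
    data.frame(parameter = parameter, transform = transform,
               mean_native = mean_native, var_est = var_est)
  perc <- switch(model$perceptual,
    hgf3 = rbind(row("kappa", "log", 0.5, 1),
                 row("omega", "identity", -2, 100),
                 row("theta", "logit", 0.5, 1),
                 row("mu2_0", "identity", 0, 1),
                 row("sa2_0", "log", 1, 1),
                 row("mu3_0", "identity", 1, 1),
                 row("sa3_0", "log", 1, 1)),
    hgf2 = rbind(row("kappa", "log", 0.5, 0),
                 row("omega", "identity", -2, 100),
                 row("theta", "logit", 0.5, 0),
                 row("mu2_0", "identity", 0, 1),
                 row("sa2_0", "log", 1, 1),
                 row("mu3_0", "identity", 1, 0),
                 row("sa3_0", "log", 1, 0)),
    rw = rbind(row("alpha", "logit", 0.2, 1),
               row("v_0", "logit", 0.5, 1)))
  zeta <- switch(model$info,
                 integrated = row("zeta", "logit", 0.5, 1),
                 advice_only = row("zeta", "identity", 1, 0),
                 cue_only = row("zeta", "identity", 0, 0))
  if (model$info == "cue_only" && model$noise == "fixed")
    perc$var_est <- 0
  out <- rbind(perc, zeta, row("beta0", "log", 48, 1))
  out$fixed <- out$var_est == 0
  class(out) <- c("prior_spec", "data.frame")
  out
}
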