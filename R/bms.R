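## Random-effects Bayesian model selection over subjects: variational
## Dirichlet posterior over model frequencies, exceedance probabilities,
## and family-level inference via the agglomerative property.

#' Random-effects Bayesian model selection
#'
#' Variational fixed-point scheme for the hierarchical model in which each
#' subject's data are generated by one of K models drawn from a
#' population multinomial with Dirichlet-distributed frequencies. Given
#' the N x K matrix of log model evidences, iterate
#' `g_nk` proportional to `exp(F_nk + digamma(alpha_k) - digamma(sum(alpha)))`
#' (row-normalized) and `alpha = alpha0 + colSums(g)` until the Dirichlet
#' parameters change by less than `tol` in the max norm.
#'
#' @param F N x K matrix of log evidences (columns named by model).
#' @param alpha0 Prior Dirichlet parameters: a scalar (replicated) or a
#'   length-K vector.
#' @param tol Convergence tolerance on `max(abs(delta alpha))`.
#' @param max_iter Iteration cap; non-convergence flags the result.
#' @param exceedance_samples Monte Carlo sample count for the exceedance
#'   probabilities.
#' @param seed Seed for the exceedance Monte Carlo.
#' @return Object of class `advice_bms`: list with `alpha`, `g`
#'   (posterior model-assignment probabilities per subject), `r` (expected
#'   model frequencies `alpha / sum(alpha)`), `xp` (exceedance
#'   probabilities), `alpha0`, `iterations`, `converged`.
#' @export
#' @examples
#' F <- rbind(c(0, -3), c(0.5, -2), c(1, -4))
#' bms(F)
bms <- function(F, alpha0 = 1, tol = 1e-8, max_iter = 1e4,
                exceedance_samples = 1e6, seed = 1L) {
  F <- as.matrix(F)
  stopifnot(ncol(F) >= 2, all(is.finite(F)))
  K <- ncol(F)
  N <- nrow(F)
  if (length(alpha0) == 1) alpha0 <- rep(alpha0, K)
  stopifnot(length(alpha0) == K, all(alpha0 > 0))

  alpha <- alpha0 + N / K
  converged <- FALSE
  iter <- 0
  g <- matrix(NA_real_, N, K)
  while (iter < max_iter) {
    iter <- iter + 1
    lg <- sweep(F, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lg <- lg - apply(lg, 1, max)          # row shift for stability
    g <- exp(lg)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged)
    warning("BMS fixed-point iteration did not converge in ", max_iter,
            " iterations")

  labels <- colnames(F)
  if (is.null(labels)) labels <- paste0("model", seq_len(K))
  names(alpha) <- names(alpha0) <- labels
  colnames(g) <- labels
  xp <- exceedance_probabilities(alpha, n_samples = exceedance_samples,
                                 seed = seed)
  structure(list(alpha = alpha, g = g, r = alpha / sum(alpha), xp = xp,
                 alpha0 = alpha0, iterations = iter, converged = converged),
            class = "advice_bms")
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' The probability that each component's frequency exceeds all others
#' under `Dirichlet(alpha)`, estimated as the Monte Carlo frequency with
#' which the component is the maximum of a draw. For K = 2 this equals
#' the Beta tail probability `P(r_1 > 1/2)`, which [bms] users can obtain
#' exactly with `stats::pbeta`.
#'
#' @param alpha Dirichlet parameter vector.
#' @param n_samples Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @return Vector of exceedance probabilities summing to 1.
#' @export
exceedance_probabilities <- function(alpha, n_samples = 1e6, seed = 1L) {
  K <- length(alpha)
  set.seed(seed)
  counts <- integer(K)
  chunk <- 2.5e5
  done <- 0
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    gmat <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
    counts <- counts + tabulate(max.col(gmat), K)
    done <- done + m
  }
  stats::setNames(counts / n_samples, names(alpha))
}

#' Family-level inference by Dirichlet agglomeration
#'
#' Sums the posterior Dirichlet parameters over the models in each family
#' (the agglomerative property of the Dirichlet), yielding the posterior
#' over family frequencies; expected probabilities and exceedance
#' probabilities are then computed on the agglomerated Dirichlet. For two
#' families the exceedance probabilities are complementary.
#'
#' @param result An `advice_bms` result (model-level).
#' @param partition Named list of model-label vectors covering every model
#'   exactly once.
#' @param exceedance_samples,seed Monte Carlo settings.
#' @return An `advice_bms` over families.
#' @export
family_agglomerate <- function(result, partition,
                               exceedance_samples = 1e6, seed = 1L) {
  labels <- names(result$alpha)
  members <- unlist(partition, use.names = FALSE)
  if (length(members) != length(labels) || !setequal(members, labels) ||
      anyDuplicated(members))
    stop("partition must cover every model exactly once")
  agg <- function(v) vapply(partition, function(f) sum(v[f]), numeric(1))
  alpha_f <- agg(result$alpha)
  g_f <- sapply(partition, function(f)
    rowSums(result$g[, f, drop = FALSE]))
  if (is.null(dim(g_f))) g_f <- matrix(g_f, nrow = 1,
                                       dimnames = list(NULL, names(partition)))
  xp_f <- exceedance_probabilities(alpha_f, n_samples = exceedance_samples,
                                   seed = seed)
  structure(list(alpha = alpha_f, g = g_f, r = alpha_f / sum(alpha_f),
                 xp = xp_f, alpha0 = agg(result$alpha0),
                 iterations = result$iterations,
                 converged = result$converged),
            class = "advice_bms")
}

#' @export
print.advice_bms <- function(x, digits = 4, ...) {
  cat("<advice_bms> K = ", length(x$alpha), ", N = ", nrow(x$g),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  tab <- rbind(alpha = x$alpha, `r (expected prob)` = x$r,
               `exceedance` = x$xp)
  print(round(tab, digits))
  invisible(x)
}

#' Model- and family-level BMS report
#'
#' Runs random-effects BMS on a complete evidence matrix and, for every
#' requested partition, a family-level comparison. For family
#' comparisons the Dirichlet prior is (optionally, and by default)
#' rescaled so that each family carries equal prior mass regardless of
#' how many models it contains, avoiding a size bias in unbalanced
#' splits.
#'
#' @param F N x K evidence matrix with model labels as column names.
#' @param partitions Named list of partitions (see
#'   [default_partitions()]).
#' @param equal_family_prior Rescale the model-level prior within each
#'   family to equalize family prior mass in the family analyses.
#' @param exceedance_samples,seed Monte Carlo settings.
#' @return Object of class `advice_bms_report`: list with `model`
#'   (model-level `advice_bms` under a unit prior) and `families` (one
#'   family-level `advice_bms` per partition).
#' @export
run_bms_report <- function(F, partitions = default_partitions(),
                           equal_family_prior = TRUE,
                           exceedance_samples = 1e6, seed = 1L) {
  F <- as.matrix(F)
  if (is.null(colnames(F)))
    stop("evidence matrix must carry model labels as column names")
  if (any(!is.finite(F))) {
    bad <- which(!is.finite(F), arr.ind = TRUE)
    stop("missing or non-finite evidences for subject x model cells: ",
         paste(apply(bad, 1, paste, collapse = "/"), collapse = ", "))
  }
  model_level <- bms(F, alpha0 = 1,
                     exceedance_samples = exceedance_samples, seed = seed)
  families <- lapply(partitions, function(part) {
    miss <- setdiff(unlist(part), colnames(F))
    if (length(miss))
      stop("partition refers to models absent from the evidence matrix: ",
           paste(miss, collapse = ", "))
    if (equal_family_prior) {
      a0 <- stats::setNames(rep(NA_real_, ncol(F)), colnames(F))
      for (f in names(part)) a0[part[[f]]] <- 1 / length(part[[f]])
      res <- bms(F, alpha0 = a0,
                 exceedance_samples = exceedance_samples, seed = seed)
    } else res <- model_level
    family_agglomerate(res, part, exceedance_samples = exceedance_samples,
                       seed = seed)
  })
  structure(list(model = model_level, families = families),
            class = "advice_bms_report")
}

#' @export
print.advice_bms_report <- function(x, digits = 4, ...) {
  cat("== Model-level random-effects BMS ==\n")
  print(x$model, digits = digits)
  for (nm in names(x$families)) {
    cat("\n== Family-level inference:", nm, "==\n")
    print(x$families[[nm]], digits = digits)
  }
  invisible(x)
}
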