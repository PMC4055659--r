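## Posterior model probabilities, Bayes factors, Jeffreys labels and
## sequential design/select rounds.

#' Posterior model probabilities from log evidences
#'
#' Stable softmax of `log_evidence + log(prior)`.
#'
#' @param log_evidences Numeric vector of per-model log marginal
#'   likelihoods.
#' @param priors Model prior probabilities (nonnegative, sum 1); default
#'   equal.
#' @return Probability vector summing to 1.
#' @export
posterior_probabilities <- function(log_evidences,
                                    priors = rep(1 / length(log_evidences),
                                                 length(log_evidences))) {
  stopifnot(length(priors) == length(log_evidences))
  if (any(priors < 0)) stop("negative model priors")
  if (sum(priors) == 0) stop("all model priors are zero")
  priors <- priors / sum(priors)
  lp <- log_evidences + log(priors)
  keep <- is.finite(lp) | lp == -Inf
  if (!any(is.finite(lp))) stop("no finite posterior mass")
  w <- exp(lp - max(lp[is.finite(lp)]))
  w[!is.finite(w)] <- 0
  w / sum(w)
}

## standard Jeffreys-scale cut points on the Bayes factor
.jeffreys_breaks <- c(1, 10^0.5, 10, 10^1.5, 10^2)
.jeffreys_labels <- c("negative", "barely-worth-mentioning", "substantial",
                      "strong", "very-strong", "decisive")

#' Jeffreys-scale label for a Bayes factor
#'
#' Standard cut points 1, 10^0.5, 10, 10^1.5 and 100: below 1 the evidence
#' is "negative" (it supports the other model; the reciprocal's label
#' applies there), and above 100 it is "decisive".
#'
#' @param bayes_factor Positive Bayes factor (vectorised).
#' @return Character label(s), one of `negative`,
#'   `barely-worth-mentioning`, `substantial`, `strong`, `very-strong`,
#'   `decisive`.
#' @export
jeffreys_label <- function(bayes_factor) {
  if (any(!is.finite(bayes_factor) & bayes_factor != Inf) ||
      any(bayes_factor <= 0))
    stop("jeffreys_label: Bayes factor must be positive")
  idx <- findInterval(bayes_factor, .jeffreys_breaks, left.open = FALSE) + 1L
  .jeffreys_labels[idx]
}

#' One round of Bayesian model selection
#'
#' Computes each model's log evidence for the dataset under the
#' experiment (via the UT prior predictive; stochastic construction is
#' used automatically for models with process noise), then posterior
#' probabilities, the pairwise Bayes-factor matrix and Jeffreys labels.
#'
#' @param models List of `utd_ssm`.
#' @param eps The [experiment()] that generated `D`.
#' @param D A [dataset()].
#' @param priors Model prior probabilities (default equal).
#' @param params [ut_params()].
#' @return Object of class `utd_selection_result` with `model_names`,
#'   `log_evidences`, `model_priors`, `posteriors`, `bayes_factors`,
#'   `jeffreys_labels`.
#' @export
run_selection_round <- function(models, eps, D,
                                priors = rep(1 / length(models),
                                             length(models)),
                                params = ut_params()) {
  log_ev <- vapply(models, function(mod) {
    pred <- prior_predictive_stochastic(mod, eps, params)
    log_marginal_likelihood(pred, D)
  }, numeric(1))
  post <- posterior_probabilities(log_ev, priors)
  M <- length(models)
  BF <- exp(outer(log_ev, log_ev, "-"))
  lab <- matrix(jeffreys_label(pmax(BF, .Machine$double.xmin)), M, M)
  diag(lab) <- "barely-worth-mentioning"
  nm <- vapply(models, `[[`, character(1), "name")
  dimnames(BF) <- dimnames(lab) <- list(nm, nm)
  structure(list(model_names = nm, log_evidences = log_ev,
                 model_priors = priors / sum(priors), posteriors = post,
                 bayes_factors = BF, jeffreys_labels = lab),
            class = "utd_selection_result")
}

#' @export
print.utd_selection_result <- function(x, ...) {
  df <- data.frame(model = x$model_names,
                   log_evidence = round(x$log_evidences, 3),
                   posterior = round(x$posteriors, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Sequential rounds of experimental design and model selection
#'
#' Round `r` designs an experiment for the currently supported model
#' subset, simulates data from the true system under that experiment, runs
#' a selection round, and carries the posteriors forward as the next
#' round's priors (renormalised over the retained set).  Models are
#' retained either by posterior threshold (`support_threshold`) or, if
#' `top_k` is given, as the `top_k` highest-posterior models.
#'
#' @param models Candidate `utd_ssm` list.
#' @param true_system The data-generating `utd_ssm`.
#' @param theta_true Parameters of the true system (default: prior
#'   component-1 mean).
#' @param n_rounds Number of rounds (>= 1).
#' @param bounds An [experiment_bounds()].
#' @param seed Integer seed (round `r` uses `seed + r - 1` offsets for the
#'   GA and the data draw).
#' @param config A [ga_config()].
#' @param support_threshold Posterior needed to stay in play (default
#'   0.1).
#' @param top_k Optional fixed number of models to retain instead.
#' @param params [ut_params()].
#' @return List of per-round lists with elements `design`
#'   (`utd_design_result`), `selection` (`utd_selection_result`),
#'   `dataset`, and `active` (indices into `models`).
#' @export
sequential_rounds <- function(models, true_system, theta_true = NULL,
                              n_rounds = 2L, bounds, seed = 1L,
                              config = ga_config(), support_threshold = 0.1,
                              top_k = NULL, params = ut_params()) {
  stopifnot(n_rounds >= 1)
  if (is.null(theta_true))
    theta_true <- true_system$parameter_prior$components[[1]]$mean
  active <- seq_along(models)
  priors <- rep(1 / length(models), length(models))
  out <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    des <- optimize_experiment(models[active], bounds, config = config,
                               seed = seed + (r - 1L) * 1000L,
                               params = params)
    D <- simulate_dataset(true_system, theta_true, des$best_eps,
                          seed = seed + (r - 1L) * 1000L + 1L)
    sel <- run_selection_round(models[active], des$best_eps, D,
                               priors = priors, params = params)
    out[[r]] <- list(design = des, selection = sel, dataset = D,
                     active = active)
    keep <- if (!is.null(top_k)) {
      order(sel$posteriors, decreasing = TRUE)[seq_len(min(top_k,
                                                           length(active)))]
    } else which(sel$posteriors > support_threshold)
    if (!length(keep))
      stop("sequential_rounds: no model above the support threshold")
    priors <- sel$posteriors[keep] / sum(sel$posteriors[keep])
    active <- active[keep]
  }
  out
}
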