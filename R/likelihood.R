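## Prior predictive distributions and marginal likelihoods.
##
## Deterministic models: one unscented transform per prior mixture
## component maps the parameter distribution straight onto the stacked
## observation vector.  Stochastic models: the UT is applied iteratively
## through the state-transition function to build Gaussian joints over
## consecutive (augmented) states, which are chained through the Markov
## property into a joint Gaussian over all measurement times.

#' Prior predictive distribution (container)
#'
#' A Gaussian mixture over the stacked observation vector
#' `(y_{t1}, ..., y_{tT})` (time-major) for one model under one
#' experiment.  Component covariances include the measurement-noise
#' contribution.
#'
#' @name PredictiveDistribution
#' @keywords internal
NULL

new_predictive <- function(mixture, eps, model_name, times, obs_dims) {
  structure(list(mixture = mixture, experiment = eps,
                 model_name = model_name, times = times, obs_dims = obs_dims),
            class = "utd_predictive")
}

#' @export
print.utd_predictive <- function(x, ...) {
  cat("Prior predictive for '", x$model_name, "': dimension ",
      length(x$mixture$components[[1]]$mean), ", ",
      length(x$mixture$weights), " component(s)\n", sep = "")
  invisible(x)
}

## observation matrices and stacked dimension bookkeeping for (model, eps)
obs_setup <- function(model, eps) {
  times <- measurement_times(eps)
  Fs <- lapply(seq_along(times), function(ti) model$observation_matrix(eps, ti))
  list(times = times, Fs = Fs, dims = vapply(Fs, nrow, integer(1)))
}

## block-diagonal stacked measurement-noise covariance
stacked_meas_cov <- function(model, dims) {
  total <- sum(dims)
  R <- matrix(0, total, total)
  off <- 0L
  for (m in dims) {
    R[off + seq_len(m), off + seq_len(m)] <- meas_cov(model, m)
    off <- off + m
  }
  R
}

#' Prior predictive distribution of a deterministic state-space model
#'
#' For each prior component, the parameter-to-stacked-observation map
#' `theta -> (F_1 x_1(theta), ..., F_T x_T(theta))` is propagated with the
#' unscented transform; the block-diagonal measurement-noise covariance is
#' added to each component covariance and the prior weights are carried
#' over.
#'
#' @param model A `utd_ssm` with zero process-noise covariance.
#' @param eps An [experiment()].
#' @param params [ut_params()].
#' @return A `utd_predictive`.
#' @export
prior_predictive_deterministic <- function(model, eps, params = ut_params()) {
  if (max(abs(model$process_noise_cov)) != 0)
    stop("prior_predictive_deterministic: model has nonzero process noise")
  os <- obs_setup(model, eps)
  Rstack <- stacked_meas_cov(model, os$dims)
  f <- function(theta) {
    theta <- clip_theta(model, theta)
    states <- model$simulate(theta, eps, os$times)
    unlist(lapply(seq_along(os$times), function(ti)
      as.numeric(os$Fs[[ti]] %*% states[ti, ])))
  }
  prior <- model$parameter_prior
  comps <- lapply(prior$components, function(g) {
    res <- ut_propagate(sigma_points(g, params), f)
    gaussian(res$gaussian$mean, res$gaussian$cov + Rstack)
  })
  new_predictive(gaussian_mixture(prior$weights, comps), eps, model$name,
                 os$times, os$dims)
}

#' Prior predictive distribution of a stochastic state-space model
#'
#' Implements the iterative joint-UT construction for models with additive
#' Gaussian process noise and observations that are linear in the state.
#' Per prior component the augmented variable `z_t = (x_t, theta)` is
#' propagated one inter-measurement interval at a time; each step yields a
#' Gaussian joint over `(z_t, z_{t+1})` whose conditionals are chained
#' through the Markov property (product of Gaussians) into a joint
#' Gaussian over all measurement-time states.  Observation moments follow
#' from linearity: `E y_t = F_t E x_t` and
#' `Cov(y_s, y_t) = F_s Cov(x_s, x_t) F_t' + delta_st R`.
#'
#' With an exactly zero process-noise covariance the construction
#' degenerates to the deterministic case and dispatches to
#' [prior_predictive_deterministic()].
#'
#' @inheritParams prior_predictive_deterministic
#' @return A `utd_predictive`.
#' @export
prior_predictive_stochastic <- function(model, eps, params = ut_params()) {
  Q <- model$process_noise_cov
  if (max(abs(Q)) == 0)
    return(prior_predictive_deterministic(model, eps, params))
  os <- obs_setup(model, eps)
  n <- model$n_states
  Tn <- length(os$times)
  prior <- model$parameter_prior
  L <- length(prior$components[[1]]$mean)
  d <- n + L
  xi <- seq_len(n)                      # x block within z
  comps <- lapply(prior$components, function(g) {
    m_prev <- c(model$initial_state, g$mean)
    C_prev <- matrix(0, d, d)
    C_prev[n + seq_len(L), n + seq_len(L)] <- g$cov
    means <- vector("list", Tn); covs <- vector("list", Tn)
    Bs <- vector("list", Tn)
    t0 <- 0
    for (s in seq_len(Tn)) {
      t1 <- os$times[s]
      f <- function(z) {
        theta <- clip_theta(model, z[n + seq_len(L)])
        c(model$state_transition(z[xi], theta, eps, t0, t1), z[n + seq_len(L)])
      }
      res <- ut_propagate(sigma_points(gaussian(m_prev, C_prev), params), f)
      Cnew <- res$gaussian$cov
      Cnew[xi, xi] <- Cnew[xi, xi] + Q
      ## regression of z_s on z_{s-1}: B = J' C_prev^- .  The pseudo-inverse
      ## uses a coarse relative tolerance: rank-deficient joints arise
      ## whenever states are deterministic functions of theta, and their
      ## null directions carry only O(1e-10) sigma-point round-off that a
      ## sharp pseudo-inverse would amplify into the chained covariance.
      Bs[[s]] <- t(MASS::ginv(C_prev, tol = 1e-6) %*% res$cross_cov)
      means[[s]] <- res$gaussian$mean
      covs[[s]] <- Cnew
      m_prev <- res$gaussian$mean
      C_prev <- Cnew
      t0 <- t1
    }
    ## chain pairwise joints into the full joint over x at measurement times
    mu <- numeric(Tn * n)
    Sig <- matrix(0, Tn * n, Tn * n)
    blocks <- vector("list", Tn)        # blocks[[s]][[t]] = Cov(z_s, z_t)
    for (s in seq_len(Tn)) {
      blocks[[s]] <- vector("list", Tn)
      blocks[[s]][[s]] <- covs[[s]]
      if (s < Tn) for (t in (s + 1):Tn)
        blocks[[s]][[t]] <- blocks[[s]][[t - 1]] %*% t(Bs[[t]])
    }
    for (s in seq_len(Tn)) {
      mu[(s - 1) * n + xi] <- means[[s]][xi]
      for (t in s:Tn) {
        blk <- blocks[[s]][[t]][xi, xi, drop = FALSE]
        Sig[(s - 1) * n + xi, (t - 1) * n + xi] <- blk
        if (t > s) Sig[(t - 1) * n + xi, (s - 1) * n + xi] <- t(blk)
      }
    }
    ## map through the stacked observation matrix and add measurement noise
    total <- sum(os$dims)
    Fstack <- matrix(0, total, Tn * n)
    off <- 0L
    for (ti in seq_len(Tn)) {
      Fstack[off + seq_len(os$dims[ti]), (ti - 1) * n + xi] <- os$Fs[[ti]]
      off <- off + os$dims[ti]
    }
    ycov <- Fstack %*% Sig %*% t(Fstack) + stacked_meas_cov(model, os$dims)
    gaussian(as.numeric(Fstack %*% mu), psd_clip(ycov, force = TRUE))
  })
  new_predictive(gaussian_mixture(prior$weights, comps), eps, model$name,
                 os$times, os$dims)
}

#' Marginalise a prior predictive onto a subset of its measurement times
#'
#' Gaussian mixtures marginalise by coordinate selection, so the
#' predictive for a shorter, nested measurement schedule is a sub-block of
#' the full one.  Used by the robustness studies to share one expensive
#' propagation across data sizes.
#'
#' @param pred A `utd_predictive`.
#' @param time_idx Indices into `pred$times` to keep.
#' @return A `utd_predictive` over the reduced schedule.
#' @export
marginalize_predictive <- function(pred, time_idx) {
  offs <- c(0L, cumsum(pred$obs_dims))
  keep <- unlist(lapply(time_idx, function(ti) offs[ti] + seq_len(pred$obs_dims[ti])))
  new_predictive(marginal_mixture(pred$mixture, keep), pred$experiment,
                 pred$model_name, pred$times[time_idx], pred$obs_dims[time_idx])
}

#' Log marginal likelihood of a dataset under a prior predictive
#'
#' The log density of the predictive Gaussian mixture at the stacked data
#' vector, evaluated in log space.
#'
#' @param pred A `utd_predictive` (or a raw [gaussian_mixture()] /
#'   [gaussian()] over the stacked observations).
#' @param D A [dataset()] whose stacked dimension matches.
#' @return Scalar log evidence.
#' @export
log_marginal_likelihood <- function(pred, D) {
  mix <- if (inherits(pred, "utd_predictive")) pred$mixture else pred
  if (inherits(mix, "utd_gaussian")) mix <- gaussian_mixture(1, list(mix))
  y <- stack_dataset(D)
  dim_pred <- length(mix$components[[1]]$mean)
  if (length(y) != dim_pred)
    stop("log_marginal_likelihood: data dimension ", length(y),
         " does not match predictive dimension ", dim_pred)
  dmixture_log(y, mix)
}

#' Monte-Carlo estimate of the log marginal likelihood
#'
#' The prior-sampling oracle: draws `n_samples` parameter vectors from the
#' prior, evaluates the (deterministic-model) likelihood of the data for
#' each, and averages in log space with log-sum-exp stabilisation.
#' Returns the log-evidence estimate and a delta-method standard error of
#' the log.  Seed-reproducible.
#'
#' @param model A deterministic `utd_ssm`.
#' @param eps An [experiment()].
#' @param D A [dataset()].
#' @param n_samples Number of prior draws (>= 100).
#' @param seed Integer seed.
#' @return List with `estimate` (log evidence) and `se`.
#' @export
mc_log_marginal_likelihood <- function(model, eps, D, n_samples = 10000L,
                                       seed = 1L) {
  stopifnot(n_samples >= 100)
  if (max(abs(model$process_noise_cov)) != 0)
    stop("mc_log_marginal_likelihood supports deterministic models only")
  os <- obs_setup(model, eps)
  Rs <- lapply(os$dims, function(m) meas_cov(model, m))
  y <- D$values
  with_seed(seed, {
    thetas <- rmixture(n_samples, model$parameter_prior)
    ll <- vapply(seq_len(n_samples), function(i) {
      theta <- clip_theta(model, thetas[i, ])
      states <- model$simulate(theta, eps, os$times)
      sum(vapply(seq_along(os$times), function(ti) {
        mu <- as.numeric(os$Fs[[ti]] %*% states[ti, ])
        dgauss_log(y[ti, ], gaussian(mu, Rs[[ti]]))
      }, numeric(1)))
    }, numeric(1))
    if (all(!is.finite(ll)))
      stop("all likelihoods are -Inf; increase n_samples or noise variance")
    mx <- max(ll)
    w <- exp(ll - mx)
    est <- mx + log(mean(w))
    se <- stats::sd(w) / (sqrt(n_samples) * mean(w))
    list(estimate = est, se = se)
  })
}
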