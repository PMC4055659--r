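## The scaled unscented transform: sigma points, moment propagation, and a
## seeded EM fit of Gaussian mixtures to uniform boxes (used for
## interaction-strength priors of user-supplied high-dimensional models).

#' Unscented-transform tuning parameters
#'
#' `beta = 2` is optimal for Gaussian inputs; `kappa = 0` is the common
#' convention; `alpha` controls sigma-point spread and is kept small by
#' default so that a single Gaussian component does not straddle non-local
#' nonlinear structure.
#'
#' @param alpha Spread parameter (> 0).
#' @param beta Prior-knowledge parameter for the central covariance weight.
#' @param kappa Secondary scaling parameter.
#' @return List with class `utd_ut_params`.
#' @export
ut_params <- function(alpha = 1e-3, beta = 2, kappa = 0) {
  stopifnot(alpha > 0)
  structure(list(alpha = alpha, beta = beta, kappa = kappa),
            class = "utd_ut_params")
}

#' Scaled sigma-point set for a Gaussian
#'
#' Generates the `2L + 1` scaled sigma points and their mean/covariance
#' weights for a `d = L` dimensional Gaussian: the mean, plus the mean
#' offset by plus/minus the columns of the Cholesky factor of
#' `(L + lambda) * cov`, with `lambda = alpha^2 (L + kappa) - L`.  The
#' weighted sample mean and covariance of the set reproduce the input
#' moments exactly (up to factorisation round-off).
#'
#' @param g A [gaussian()].
#' @param alpha,beta,kappa Scaled-UT parameters (see [ut_params()]).
#' @return Object of class `utd_sigma_points`: `points` (`(2L+1) x L`
#'   matrix, first row the mean), `mean_weights`, `cov_weights`, `params`.
#' @examples
#' sp <- sigma_points(gaussian(0, 1), alpha = 1, beta = 2, kappa = 2)
#' sp$points          # 0, +sqrt(3), -sqrt(3)
#' sp$mean_weights    # 2/3, 1/6, 1/6
#' @export
sigma_points <- function(g, alpha = 1e-3, beta = 2, kappa = 0) {
  if (inherits(alpha, "utd_ut_params")) {
    p <- alpha; alpha <- p$alpha; beta <- p$beta; kappa <- p$kappa
  }
  stopifnot(alpha > 0)
  L <- length(g$mean)
  lambda <- alpha^2 * (L + kappa) - L
  scale <- L + lambda
  S <- scale * g$cov
  ch <- tryCatch(chol(S), error = function(e)
    tryCatch(chol(S + diag(1e-12, L)), error = function(e2)
      stop("sigma_points: covariance not PSD even after jitter")))
  ## chol() returns upper-triangular R with S = R'R; rows of R are the
  ## required "columns" of a matrix square root.
  pts <- matrix(g$mean, 2 * L + 1, L, byrow = TRUE)
  for (i in seq_len(L)) {
    pts[1 + i, ] <- g$mean + ch[i, ]
    pts[1 + L + i, ] <- g$mean - ch[i, ]
  }
  wm <- c(lambda / scale, rep(1 / (2 * scale), 2 * L))
  wc <- wm
  wc[1] <- wc[1] + 1 - alpha^2 + beta
  structure(list(points = pts, mean_weights = wm, cov_weights = wc,
                 params = list(alpha = alpha, beta = beta, kappa = kappa,
                               lambda = lambda, L = L)),
            class = "utd_sigma_points")
}

#' Propagate a sigma-point set through a nonlinear map
#'
#' Applies `f` to every sigma point and forms the weighted mean and
#' covariance of the images, together with the input-output
#' cross-covariance (needed by the stochastic evidence construction).
#' The estimate is exact for affine `f` and accurate to second order in
#' the Taylor expansion otherwise.  A negative central covariance weight
#' (small `alpha`) can produce slightly indefinite output covariances;
#' these are eigenvalue-clipped at zero.
#'
#' @param sp A [sigma_points()] set.
#' @param f Function mapping an input vector to an output vector (constant
#'   output dimension).
#' @return List of class `utd_ut_result`: `gaussian` (output moments),
#'   `cross_cov` (input x output), `propagated` (matrix of images).
#' @export
ut_propagate <- function(sp, f) {
  n <- nrow(sp$points)
  y1 <- f(sp$points[1, ])
  if (any(!is.finite(y1)))
    stop("ut_propagate: non-finite output at sigma point 1")
  Y <- matrix(0, n, length(y1))
  Y[1, ] <- y1
  for (i in 2:n) {
    yi <- f(sp$points[i, ])
    if (any(!is.finite(yi)))
      stop("ut_propagate: non-finite output at sigma point ", i)
    Y[i, ] <- yi
  }
  mu <- as.numeric(crossprod(Y, sp$mean_weights))
  dev <- sweep(Y, 2, mu)
  cv <- crossprod(dev, dev * sp$cov_weights)
  cv <- psd_clip((cv + t(cv)) / 2, force = TRUE)
  xdev <- sweep(sp$points, 2, as.numeric(crossprod(sp$points, sp$mean_weights)))
  cc <- crossprod(xdev * sp$cov_weights, dev)
  structure(list(gaussian = gaussian(mu, cv), cross_cov = cc, propagated = Y),
            class = "utd_ut_result")
}

#' Propagate a Gaussian mixture through a nonlinear map
#'
#' Componentwise unscented transform; weights are carried unchanged.
#'
#' @param m A [gaussian_mixture()].
#' @param f Map as in [ut_propagate()].
#' @param params [ut_params()].
#' @return A [gaussian_mixture()] over the output space.
#' @export
ut_propagate_mixture <- function(m, f, params = ut_params()) {
  comps <- lapply(m$components, function(g) {
    sp <- sigma_points(g, params)
    ut_propagate(sp, f)$gaussian
  })
  gaussian_mixture(m$weights, comps)
}

#' Fit a Gaussian mixture to a uniform box distribution
#'
#' Draws `n_sample` uniform points on the hyper-rectangle
#' `[lower, upper]` and fits a `K`-component Gaussian mixture by EM
#' (k-means initialisation, covariance floor `1e-8` on the diagonal,
#' at most `max_iter` iterations).  Deterministic given `seed`.  Used for
#' interaction-strength priors where a bounded-support belief must be
#' expressed inside a Gaussian-mixture machinery.
#'
#' @param lower,upper Numeric vectors of equal length, `lower < upper`.
#' @param K Number of components (>= 1).
#' @param n_sample Number of uniform draws.
#' @param seed Integer seed.
#' @param max_iter Maximum EM iterations.
#' @return A [gaussian_mixture()].
#' @export
fit_mixture_to_box <- function(lower, upper, K, n_sample = 4000L, seed = 1L,
                               max_iter = 200L) {
  stopifnot(length(lower) == length(upper), all(lower < upper), K >= 1)
  d <- length(lower)
  with_seed(seed, {
    X <- matrix(runif(n_sample * d), n_sample, d)
    X <- sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+")
    for (attempt in 1:5) {
      fit <- try(.em_gmm(X, K, max_iter), silent = TRUE)
      if (!inherits(fit, "try-error")) return(fit)
    }
    stop("fit_mixture_to_box: EM failed repeatedly (degenerate components)")
  })
}

## plain EM for a full-covariance GMM; kmeans init from the seeded sample
.em_gmm <- function(X, K, max_iter) {
  n <- nrow(X); d <- ncol(X)
  if (K == 1L) {
    return(gaussian_mixture(1, list(gaussian(colMeans(X),
                                             stats::cov(X) * (n - 1) / n))))
  }
  km <- kmeans(X, centers = K, nstart = 3, iter.max = 50)
  w <- as.numeric(table(factor(km$cluster, levels = 1:K))) / n
  mu <- km$centers
  Sg <- lapply(1:K, function(k) {
    idx <- km$cluster == k
    if (sum(idx) < 2) diag(1e-2, d)
    else stats::cov(X[idx, , drop = FALSE]) + diag(1e-8, d)
  })
  ## vectorised multivariate-normal log density over the rows of X
  ldens <- function(mu_k, S_k) {
    ch <- chol(S_k)
    z <- backsolve(ch, t(X) - mu_k, transpose = TRUE)
    -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logp <- vapply(1:K, function(k) ldens(mu[k, ], Sg[[k]]) + log(w[k]),
                   numeric(n))
    mx <- do.call(pmax, as.data.frame(logp))
    lsev <- mx + log(rowSums(exp(logp - mx)))
    r <- exp(logp - lsev)
    nk <- colSums(r)
    if (any(nk < d + 1)) stop("degenerate EM component")
    w <- nk / n
    for (k in 1:K) {
      mu[k, ] <- colSums(X * r[, k]) / nk[k]
      dv <- sweep(X, 2, mu[k, ])
      Sg[[k]] <- crossprod(dv, dv * r[, k]) / nk[k] + diag(1e-8, d)
    }
    ll <- sum(lsev)
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-8 * abs(ll)) break
    ll_old <- ll
  }
  w <- w / sum(w)
  gaussian_mixture(w, lapply(1:K, function(k) gaussian(mu[k, ], Sg[[k]])))
}

## run expr under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Split a Gaussian into a moment-matched three-component mixture
#'
#' Replaces `N(mu, Sigma)` by the mixture
#' `0.5 N(mu, Sigma') + 0.25 N(mu + delta, Sigma') + 0.25 N(mu - delta, Sigma')`
#' with `delta = Sigma u / sd_u` and
#' `Sigma' = Sigma - 0.5 (Sigma u)(Sigma u)' / sd_u^2`, where
#' `sd_u^2 = u' Sigma u`.  The mixture reproduces the original mean and
#' covariance exactly while halving the variance along `u`, which reduces
#' the unscented transform's higher-order error for maps that are
#' nonlinear along that direction.
#'
#' @param g A [gaussian()].
#' @param u Split direction (need not be normalised).
#' @return A three-component [gaussian_mixture()].
#' @export
split_gaussian <- function(g, u) {
  u <- as.numeric(u)
  sd2 <- as.numeric(t(u) %*% g$cov %*% u)
  if (sd2 <= 0) stop("split_gaussian: zero variance along split direction")
  Su <- as.numeric(g$cov %*% u)
  shift <- Su / sqrt(sd2)
  covn <- g$cov - 0.5 * outer(Su, Su) / sd2
  gaussian_mixture(c(0.5, 0.25, 0.25),
                   list(gaussian(g$mean, covn),
                        gaussian(g$mean + shift, covn),
                        gaussian(g$mean - shift, covn)))
}

#' Direction of strongest parameter-to-observation coupling
#'
#' Runs a pilot unscented transform of the deterministic
#' parameter-to-stacked-observation map and returns the regression
#' direction `Sigma^- C w1` in parameter space, where `C` is the
#' input-output cross-covariance and `w1` its leading right singular
#' vector.  Splitting the prior along this direction targets the
#' nonlinearity that actually reaches the observations.
#'
#' @param model A deterministic `utd_ssm`.
#' @param eps An [experiment()].
#' @param component Which prior component to analyse (default 1).
#' @param params [ut_params()].
#' @return Unit vector in parameter space.
#' @export
nonlinearity_direction <- function(model, eps, component = 1L,
                                   params = ut_params()) {
  g <- model$parameter_prior$components[[component]]
  os <- obs_setup(model, eps)
  f <- function(theta) {
    theta <- clip_theta(model, theta)
    states <- model$simulate(theta, eps, os$times)
    unlist(lapply(seq_along(os$times), function(ti)
      as.numeric(os$Fs[[ti]] %*% states[ti, ])))
  }
  pil <- ut_propagate(sigma_points(g, params), f)
  w1 <- svd(pil$cross_cov)$v[, 1]
  u <- as.numeric(MASS::ginv(g$cov) %*% (pil$cross_cov %*% w1))
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("nonlinearity_direction: degenerate cross-covariance")
  u / nu
}

#' Refine a model's parameter prior by recursive component splitting
#'
#' Applies [split_gaussian()] `depth` times along the model's
#' [nonlinearity_direction()] under the given experiment, multiplying the
#' component count by 3 per level (`K = 3^depth` per original component).
#' The refined prior has identical first and second moments; only the UT
#' approximation of the prior predictive changes.
#'
#' @param model A deterministic `utd_ssm`.
#' @param eps An [experiment()].
#' @param depth Number of split levels (0 returns the model unchanged).
#' @param params [ut_params()].
#' @return The model with a refined `parameter_prior`.
#' @export
refine_parameter_prior <- function(model, eps, depth = 1L,
                                   params = ut_params()) {
  if (depth < 1) return(model)
  u <- nonlinearity_direction(model, eps, params = params)
  mix <- model$parameter_prior
  for (lev in seq_len(depth)) {
    ws <- c(); comps <- list()
    for (i in seq_along(mix$weights)) {
      s <- split_gaussian(mix$components[[i]], u)
      ws <- c(ws, mix$weights[i] * s$weights)
      comps <- c(comps, s$components)
    }
    mix <- gaussian_mixture(ws, comps)
  }
  model$parameter_prior <- mix
  model
}
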