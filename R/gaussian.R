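## Gaussian and Gaussian-mixture containers.
##
## These are deliberately plain S3 lists: every higher-level object in the
## package (parameter priors, prior predictive distributions, UT outputs)
## is built from them, and they are serialised to JSON by the IO layer.

#' Multivariate Gaussian distribution
#'
#' A minimal container for a mean vector and a symmetric positive
#' semi-definite covariance matrix.  Covariances are symmetrised and
#' eigenvalue-clipped at zero on construction (tolerance `-1e-10`; more
#' negative eigenvalues are an error), so downstream code can rely on PSD
#' inputs.
#'
#' @param mean Numeric vector (length `d`).
#' @param cov `d x d` covariance matrix (a scalar is promoted to a `1 x 1`
#'   matrix, a vector to a diagonal matrix).
#' @return An object of class `utd_gaussian` with elements `mean` and `cov`.
#' @examples
#' g <- gaussian(c(0, 1), diag(2))
#' g$mean
#' @export
gaussian <- function(mean, cov) {
  mean <- as.numeric(mean)
  d <- length(mean)
  if (is.null(dim(cov))) {
    cov <- if (length(cov) == 1L) diag(as.numeric(cov), d) else diag(as.numeric(cov))
  }
  cov <- as.matrix(cov)
  if (!all(dim(cov) == c(d, d)))
    stop("gaussian: cov must be ", d, " x ", d)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("gaussian: cov is not symmetric")
  cov <- psd_clip((cov + t(cov)) / 2)
  structure(list(mean = mean, cov = cov), class = "utd_gaussian")
}

#' @export
print.utd_gaussian <- function(x, ...) {
  cat("Gaussian, dimension", length(x$mean), "\n")
  cat("  mean:", format(x$mean, digits = 4), "\n")
  invisible(x)
}

#' Clip a symmetric matrix to the PSD cone
#'
#' Eigenvalues in `[-1e-10, 0)` are clipped to zero; more negative
#' eigenvalues signal a genuinely indefinite matrix and raise an error
#' unless `force = TRUE` (used internally where small indefiniteness is an
#' expected by-product of negative sigma-point weights).
#'
#' @param m Symmetric matrix.
#' @param tol Most negative eigenvalue accepted without `force`.
#' @param force Clip regardless of magnitude.
#' @return PSD matrix.
#' @export
psd_clip <- function(m, tol = 1e-10, force = FALSE) {
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  lam <- ev$values
  if (min(lam) >= 0) return(m)
  if (!force && min(lam) < -tol * max(1, max(abs(lam))))
    stop("matrix has eigenvalue ", format(min(lam)), "; not PSD within tolerance")
  lam[lam < 0] <- 0
  m <- ev$vectors %*% (lam * t(ev$vectors))
  (m + t(m)) / 2
}

#' Gaussian mixture distribution
#'
#' @param weights Nonnegative weights; must sum to 1 within `1e-12` (they
#'   are not renormalised silently).
#' @param components List of [gaussian()] objects of equal dimension.
#' @return An object of class `utd_mixture`.
#' @examples
#' m <- gaussian_mixture(c(0.4, 0.6), list(gaussian(0, 1), gaussian(3, 2)))
#' @export
gaussian_mixture <- function(weights, components) {
  weights <- as.numeric(weights)
  if (any(weights < 0)) stop("mixture weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12) stop("mixture weights must sum to 1")
  if (length(weights) != length(components))
    stop("length(weights) != length(components)")
  if (!all(vapply(components, inherits, logical(1), "utd_gaussian")))
    stop("components must be utd_gaussian objects")
  d <- unique(vapply(components, function(g) length(g$mean), integer(1)))
  if (length(d) != 1L) stop("mixture components have unequal dimensions")
  structure(list(weights = weights, components = components),
            class = "utd_mixture")
}

#' @export
print.utd_mixture <- function(x, ...) {
  cat("Gaussian mixture:", length(x$weights), "component(s), dimension",
      length(x$components[[1]]$mean), "\n")
  invisible(x)
}

#' Number of mixture components
#' @param m A `utd_mixture`.
#' @return Integer count.
#' @export
n_components <- function(m) length(m$weights)

## log N(x; mean, cov) via Cholesky; jitter only as a last resort for
## numerically singular covariances (evidence values are exponentially
## sensitive, so the jitter is tiny and deterministic).
dgauss_log <- function(x, g) {
  d <- length(g$mean)
  if (length(x) != d) stop("dgauss_log: dimension mismatch")
  ch <- tryCatch(chol(g$cov), error = function(e) chol(g$cov + diag(1e-12, d)))
  z <- backsolve(ch, x - g$mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Log density of a Gaussian mixture
#'
#' Evaluated stably in log space (log-sum-exp over components).
#'
#' @param x Numeric vector (a single point).
#' @param m A [gaussian_mixture()] (a plain `utd_gaussian` is accepted).
#' @return Scalar log density.
#' @export
dmixture_log <- function(x, m) {
  if (inherits(m, "utd_gaussian")) return(dgauss_log(x, m))
  lse(log(m$weights) + vapply(m$components, function(g) dgauss_log(x, g),
                              numeric(1)))
}

## log-sum-exp
lse <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(-Inf)
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}

#' Draw samples from a Gaussian mixture
#'
#' @param n Number of draws.
#' @param m A [gaussian_mixture()] or [gaussian()].
#' @return `n x d` matrix of draws (uses the current RNG state).
#' @export
rmixture <- function(n, m) {
  if (inherits(m, "utd_gaussian"))
    m <- gaussian_mixture(1, list(m))
  d <- length(m$components[[1]]$mean)
  comp <- sample.int(length(m$weights), n, replace = TRUE, prob = m$weights)
  out <- matrix(0, n, d)
  for (k in unique(comp)) {
    idx <- which(comp == k)
    g <- m$components[[k]]
    ch <- tryCatch(chol(g$cov), error = function(e) chol(g$cov + diag(1e-12, d)))
    z <- matrix(rnorm(length(idx) * d), length(idx), d)
    out[idx, ] <- sweep(z %*% ch, 2, g$mean, "+")
  }
  out
}

#' Moments of a Gaussian mixture
#'
#' Overall mean and covariance (law of total variance).
#'
#' @param m A [gaussian_mixture()].
#' @return A [gaussian()] with the mixture's first two moments.
#' @export
mixture_moments <- function(m) {
  mus <- vapply(m$components, `[[`, numeric(length(m$components[[1]]$mean)),
                "mean")
  mus <- matrix(mus, nrow = length(m$components[[1]]$mean))
  mu <- as.numeric(mus %*% m$weights)
  d <- length(mu)
  cv <- matrix(0, d, d)
  for (k in seq_along(m$weights)) {
    dm <- mus[, k] - mu
    cv <- cv + m$weights[k] * (m$components[[k]]$cov + tcrossprod(dm))
  }
  gaussian(mu, cv)
}

## marginal of a Gaussian / mixture on a coordinate subset
marginal_gaussian <- function(g, idx) gaussian(g$mean[idx], g$cov[idx, idx, drop = FALSE])

marginal_mixture <- function(m, idx) {
  if (inherits(m, "utd_gaussian")) return(marginal_gaussian(m, idx))
  gaussian_mixture(m$weights, lapply(m$components, marginal_gaussian, idx = idx))
}
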