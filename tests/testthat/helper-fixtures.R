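## Shared fixtures, built in code.  Heavier objects are memoised per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

six_models <- function() memo("six", crosstalk_six_models())

## the hand-picked separating experiment used for recovery checks:
## both stimuli at full strength, 20 measurements of pathway-2 species
## 2, 3 and 4
separating_experiment <- function() {
  obs <- matrix(0, 3, 8)
  obs[1, 6] <- obs[2, 7] <- obs[3, 8] <- 1
  experiment(stimulus_strengths = c(5, 5), delay = 15, t_obs = 2,
             n_timepoints = 20L, spacing = 4, observation = obs)
}

## single-measurement fixture for UT-vs-MC comparisons (near steady state,
## where the single-component predictive is closest to Gaussian)
mc_fixture_experiment <- function() {
  experiment(stimulus_strengths = c(5, 5), delay = 10, t_obs = 30,
             n_timepoints = 1L, spacing = 8)
}

## A state-space model whose stacked observation map is affine in theta:
## x_t(theta) = t * (M theta + b), observed directly.  The prior predictive
## and the evidence then have exact linear-Gaussian closed forms.
affine_ssm <- function(M = rbind(c(1, 0.5), c(-0.3, 2)),
                       b = c(0.2, -0.1),
                       prior = gaussian(c(1, -1), diag(c(0.5, 0.25))),
                       noise_var = 0.04) {
  n <- nrow(M)
  state_space_model(
    name = "affine", n_states = n,
    simulate = function(theta, eps, times) {
      base <- as.numeric(M %*% theta + b)
      do.call(rbind, lapply(times, function(t) t * base))
    },
    state_transition = function(x, theta, eps, t0, t1) {
      if (t1 == t0) return(x)
      x / max(t0, 1) * t1
    },
    observation_matrix = function(eps, ti) diag(n),
    parameter_prior = prior, measurement_noise = noise_var,
    initial_state = rep(0, n))
}

## closed-form linear-Gaussian evidence for the affine model
affine_evidence <- function(model, eps, D,
                            M = rbind(c(1, 0.5), c(-0.3, 2)),
                            b = c(0.2, -0.1)) {
  times <- measurement_times(eps)
  g0 <- model$parameter_prior$components[[1]]
  Mfull <- do.call(rbind, lapply(times, function(t) t * M))
  bfull <- unlist(lapply(times, function(t) t * b))
  mu <- as.numeric(Mfull %*% g0$mean + bfull)
  R <- diag(model$measurement_noise, length(mu))
  S <- Mfull %*% g0$cov %*% t(Mfull) + R
  y <- as.numeric(t(D$values))
  utdesign:::dgauss_log(y, gaussian(mu, S))
}

## linear stochastic SSM with fixed dynamics (zero-variance prior) for the
## Kalman-prediction oracle
kalman_ssm <- function(A = matrix(c(0.9, 0.2, 0, 0.7), 2, 2),
                       Q = diag(c(0.05, 0.02)), R = 0.01,
                       Fm = matrix(c(1, 0), 1, 2), x0 = c(1, -0.5)) {
  step <- function(x, t0, t1) {
    for (s in seq_len(round(t1 - t0))) x <- as.numeric(A %*% x)
    x
  }
  state_space_model(
    name = "kalman", n_states = nrow(A),
    simulate = function(theta, eps, times) {
      x <- x0; t0 <- 0
      out <- matrix(0, length(times), nrow(A))
      for (j in seq_along(times)) {
        x <- step(x, t0, times[j]); out[j, ] <- x; t0 <- times[j]
      }
      out
    },
    state_transition = function(x, theta, eps, t0, t1) step(x, t0, t1),
    observation_matrix = function(eps, ti) Fm,
    parameter_prior = gaussian(0, matrix(0, 1, 1)),
    process_noise_cov = Q, measurement_noise = R, initial_state = x0)
}

## exact stacked observation moments of the Kalman model over integer times
## 1..Ts (prediction form: no conditioning on data)
kalman_prediction_moments <- function(A, Q, R, Fm, x0, Ts) {
  n <- nrow(A)
  x <- x0; P <- matrix(0, n, n)
  covs <- vector("list", Ts); Ms <- matrix(0, Ts, n)
  for (t in seq_len(Ts)) {
    x <- as.numeric(A %*% x)
    P <- A %*% P %*% t(A) + Q
    Ms[t, ] <- x; covs[[t]] <- P
  }
  Sig <- matrix(0, n * Ts, n * Ts)
  for (s in seq_len(Ts)) {
    idx_s <- (s - 1) * n + seq_len(n)
    Sig[idx_s, idx_s] <- covs[[s]]
    if (s < Ts) {
      C <- covs[[s]]
      for (t in (s + 1):Ts) {
        C <- C %*% t(A)
        idx_t <- (t - 1) * n + seq_len(n)
        Sig[idx_s, idx_t] <- C
        Sig[idx_t, idx_s] <- t(C)
      }
    }
  }
  m <- nrow(Fm)
  Fst <- matrix(0, m * Ts, n * Ts)
  for (t in seq_len(Ts))
    Fst[(t - 1) * m + seq_len(m), (t - 1) * n + seq_len(n)] <- Fm
  list(mean = as.numeric(Fst %*% as.numeric(t(Ms))),
       cov = Fst %*% Sig %*% t(Fst) + diag(R, m * Ts))
}

## dense-grid quadrature for 1-D Hellinger distances (independent oracle)
hellinger_quadrature_1d <- function(dens1, dens2, lo, hi, n = 20000L) {
  x <- seq(lo, hi, length.out = n)
  h <- x[2] - x[1]
  bc <- sum(sqrt(dens1(x) * dens2(x))) * h
  sqrt(max(0, 1 - bc))
}
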