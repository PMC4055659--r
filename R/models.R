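## State-space model representations and the built-in model families:
## crosstalk gene-regulatory cascades, a two-species mRNA/protein
## demonstration model, and linear-ODE base/extension systems.

#' Experiment description
#'
#' The vector of design parameters: strengths of the two stimulus pulses,
#' the onset-to-onset delay between them, the measurement schedule and the
#' observed-species selection.  Stimuli are rectangular pulses of fixed
#' duration (`stimulus_duration`, default 5 time units) added to the
#' production term of the stimulated species; the first pulse starts at
#' t = 0, the second at t = `delay`.
#'
#' @param stimulus_strengths Length-2 numeric `(s1, s2)`.
#' @param delay Nonnegative onset-to-onset delay of the second pulse.
#' @param t_obs Time of the first measurement (> 0).
#' @param n_timepoints Number of equally spaced measurements (>= 1).
#' @param spacing Spacing between measurements (> 0).
#' @param observation Observed-species selection: `NULL` for the model
#'   default, `list(species =, coef =)` for a single scaled readout, or an
#'   `m x n` coefficient matrix.
#' @param stimulus_duration Pulse length.
#' @param extras Named list of model-specific experiment hooks (e.g.
#'   `knockout`, `repressor` for the mRNA/protein model).
#' @return Object of class `utd_experiment`.
#' @export
experiment <- function(stimulus_strengths = c(0, 0), delay = 0, t_obs = 1,
                       n_timepoints = 1L, spacing = 1, observation = NULL,
                       stimulus_duration = 5, extras = list()) {
  stopifnot(t_obs > 0, n_timepoints >= 1, spacing > 0, delay >= 0)
  structure(list(stimulus_strengths = as.numeric(stimulus_strengths),
                 delay = delay, t_obs = t_obs,
                 n_timepoints = as.integer(n_timepoints), spacing = spacing,
                 observation = observation,
                 stimulus_duration = stimulus_duration, extras = extras),
            class = "utd_experiment")
}

#' Measurement times of an experiment
#' @param eps An [experiment()].
#' @return Increasing numeric vector `t_obs + spacing * (0:(n-1))`.
#' @export
measurement_times <- function(eps) {
  eps$t_obs + eps$spacing * (seq_len(eps$n_timepoints) - 1)
}

#' General state-space model
#'
#' The unit of model comparison.  `simulate` integrates the deterministic
#' dynamics from `initial_state` at time 0 and returns states at requested
#' times; `state_transition` advances an arbitrary state over one
#' inter-measurement interval (used by the stochastic evidence
#' construction and by process-noise simulation).  Observations are linear
#' in the state: `y_t = F_t x_t + eta_t`.
#'
#' @param name Model identifier.
#' @param n_states State dimension.
#' @param simulate Function `(theta, eps, times) -> T x n` state matrix.
#' @param state_transition Function `(x, theta, eps, t0, t1) -> state`;
#'   must be the identity for `t1 == t0`.
#' @param observation_matrix Function `(eps, t_index) -> m x n` matrix.
#' @param parameter_prior A [gaussian_mixture()] (or [gaussian()]) over
#'   theta.
#' @param process_noise_cov `n x n` PSD matrix; the zero matrix selects the
#'   deterministic machinery.
#' @param measurement_noise Scalar variance (isotropic) or `m x m` PSD
#'   matrix.
#' @param initial_state State at time 0.
#' @param theta_lower Optional elementwise lower bound; sigma-point
#'   excursions below it are clipped before simulation (rate parameters
#'   must stay positive for the integrator).
#' @return Object of class `utd_ssm`.
#' @export
state_space_model <- function(name, n_states, simulate, state_transition,
                              observation_matrix, parameter_prior,
                              process_noise_cov = NULL,
                              measurement_noise = 0.01, initial_state,
                              theta_lower = NULL) {
  if (inherits(parameter_prior, "utd_gaussian"))
    parameter_prior <- gaussian_mixture(1, list(parameter_prior))
  if (is.null(process_noise_cov))
    process_noise_cov <- matrix(0, n_states, n_states)
  process_noise_cov <- psd_clip(as.matrix(process_noise_cov))
  structure(list(name = name, n_states = as.integer(n_states),
                 simulate = simulate, state_transition = state_transition,
                 observation_matrix = observation_matrix,
                 parameter_prior = parameter_prior,
                 process_noise_cov = process_noise_cov,
                 measurement_noise = measurement_noise,
                 initial_state = as.numeric(initial_state),
                 theta_lower = theta_lower),
            class = "utd_ssm")
}

#' @export
print.utd_ssm <- function(x, ...) {
  cat("State-space model '", x$name, "': ", x$n_states, " states, theta dim ",
      length(x$parameter_prior$components[[1]]$mean), "\n", sep = "")
  invisible(x)
}

## clip theta at the model's lower bound (rate positivity)
clip_theta <- function(model, theta) {
  if (is.null(model$theta_lower)) return(theta)
  pmax(theta, model$theta_lower)
}

## measurement-noise covariance as an m x m matrix
meas_cov <- function(model, m) {
  R <- model$measurement_noise
  if (is.matrix(R)) {
    if (!all(dim(R) == m)) stop("measurement noise matrix is not ", m, " x ", m)
    R
  } else diag(as.numeric(R), m)
}

## ---------------------------------------------------------------------------
## Crosstalk cascades

#' Specification of a pair of regulatory cascades
#'
#' Two transcription-factor cascades of `n_per_pathway` species each.
#' Species `i > 1` of a pathway is produced at maximal rate `v_i`
#' modulated by an activating Hill function of its upstream species
#' (half-max `k_i`, steepness `n_H`); the pathway-top species has
#' constitutive production `v_1`.  Every species degrades linearly at rate
#' `lambda_i`.  Crosstalk links insert an additional regulatory input with
#' the same kinetics: an additive activating Hill production term (the
#' target's `v`, `k` and `n_H`) driven by the source species.
#'
#' State ordering: pathway 1 species `1..n`, then pathway 2 species
#' `1..n`.
#'
#' @param n_per_pathway Species per pathway (default 4).
#' @param v,lambda,k Per-species production, degradation and half-max
#'   vectors (length `2 * n_per_pathway`; scalars are recycled).
#' @param n_H Hill coefficient (>= 1; fixed, not inferred).
#' @param crosstalk_links List of integer 4-vectors
#'   `(src_pathway, src_index, tgt_pathway, tgt_index)`.
#' @return Object of class `utd_cascade_spec`.
#' @export
cascade_spec <- function(n_per_pathway = 4L, v = 1, lambda = 0.1, k = 10,
                         n_H = 2, crosstalk_links = list()) {
  n <- 2L * as.integer(n_per_pathway)
  v <- rep_len(as.numeric(v), n)
  lambda <- rep_len(as.numeric(lambda), n)
  k <- rep_len(as.numeric(k), n)
  if (any(v <= 0) || any(lambda <= 0) || any(k <= 0))
    stop("cascade_spec: all rates must be positive")
  if (n_H < 1) stop("cascade_spec: n_H must be >= 1")
  seen <- character()
  for (l in crosstalk_links) {
    l <- as.integer(l)
    if (length(l) != 4L) stop("cascade_spec: links are 4-vectors")
    if (any(l[c(1, 3)] < 1 | l[c(1, 3)] > 2) ||
        any(l[c(2, 4)] < 1 | l[c(2, 4)] > n_per_pathway))
      stop("cascade_spec: link indices out of range")
    key <- paste(l, collapse = ".")
    if (key %in% seen) stop("cascade_spec: duplicate crosstalk link ", key)
    seen <- c(seen, key)
  }
  structure(list(n_per_pathway = as.integer(n_per_pathway), v = v,
                 lambda = lambda, k = k, n_H = n_H,
                 crosstalk_links = lapply(crosstalk_links, as.integer)),
            class = "utd_cascade_spec")
}

#' Activating Hill function
#'
#' `u^n / (k^n + u^n)`; equals 1/2 at `u = k`.  Nonpositive `u` maps to 0.
#'
#' @param u Input concentration.
#' @param k Half-max constant.
#' @param n Hill coefficient.
#' @return Value in `[0, 1)`.
#' @export
hill <- function(u, k, n) {
  out <- numeric(length(u))
  pos <- u > 0
  r <- (u[pos] / k)^n
  out[pos] <- r / (1 + r)
  out
}

## global state index of (pathway, index)
cascade_index <- function(spec, pathway, index) {
  (pathway - 1L) * spec$n_per_pathway + index
}

#' Cascade right-hand side
#'
#' Time derivative of the full two-pathway state.  Used directly by tests
#' and by the generic integrator; production sums the activating Hill
#' terms of all regulatory inputs into a species.
#'
#' @param state Nonnegative state vector (length `2 * n_per_pathway`).
#' @param spec A [cascade_spec()].
#' @param stimulus Function `time -> per-species additive production`
#'   (vector of the state length), or `NULL` for none.
#' @param t Time.
#' @return Derivative vector.
#' @export
cascade_rhs <- function(state, spec, stimulus = NULL, t = 0) {
  stopifnot(inherits(spec, "utd_cascade_spec"))
  n <- 2L * spec$n_per_pathway
  if (length(state) != n) stop("cascade_rhs: state has wrong length")
  dy <- numeric(n)
  for (i in seq_len(n)) {
    pos <- (i - 1L) %% spec$n_per_pathway + 1L
    prod_fac <- if (pos > 1L) hill(state[i - 1L], spec$k[i], spec$n_H) else 1
    for (l in spec$crosstalk_links) {
      if (cascade_index(spec, l[3], l[4]) == i)
        prod_fac <- prod_fac + hill(state[cascade_index(spec, l[1], l[2])],
                                    spec$k[i], spec$n_H)
    }
    dy[i] <- spec$v[i] * prod_fac - spec$lambda[i] * state[i]
  }
  if (!is.null(stimulus)) dy <- dy + stimulus(t)
  dy
}

#' Unstimulated steady state of a crosstalk-free cascade
#'
#' Closed-form fixed point of the chain: the top species settles at
#' `v_1 / lambda_1`, each downstream species at
#' `v_i hill(x_{i-1}) / lambda_i`.
#'
#' @param spec A [cascade_spec()] (links are ignored).
#' @param v,lambda Optional parameter overrides.
#' @return Steady-state vector.
#' @export
cascade_steady_state <- function(spec, v = spec$v, lambda = spec$lambda) {
  n <- 2L * spec$n_per_pathway
  x <- numeric(n)
  for (i in seq_len(n)) {
    pos <- (i - 1L) %% spec$n_per_pathway + 1L
    x[i] <- if (pos == 1L) v[i] / lambda[i]
            else v[i] * hill(x[i - 1L], spec$k[i], spec$n_H) / lambda[i]
  }
  x
}

## links list -> 0-based (src_global, tgt_global) integer matrix for C++
links_matrix <- function(spec) {
  if (!length(spec$crosstalk_links))
    return(matrix(0L, 0, 2))
  do.call(rbind, lapply(spec$crosstalk_links, function(l) {
    c(cascade_index(spec, l[1], l[2]) - 1L,
      cascade_index(spec, l[3], l[4]) - 1L)
  }))
}

#' Default parameter prior of the cascade family
#'
#' Independent Gaussians centred on the nominal kinetics: production rates
#' `v_i ~ N(1, 0.04)` and degradation rates `lambda_i ~ N(0.1, 4e-4)`
#' (the variance scaled so both have a 20% coefficient of variation).
#' Theta ordering: all `v`, then all `lambda`.
#'
#' @param spec A [cascade_spec()].
#' @param cv Coefficient of variation (default 0.2).
#' @return A single-component [gaussian_mixture()].
#' @export
cascade_prior <- function(spec, cv = 0.2) {
  mu <- c(spec$v, spec$lambda)
  gaussian_mixture(1, list(gaussian(mu, diag((cv * mu)^2))))
}

## stimulus vector function for an experiment (R-side mirror of the C++)
cascade_stimulus <- function(spec, eps) {
  n <- 2L * spec$n_per_pathway
  i2 <- spec$n_per_pathway + 1L
  function(t) {
    s <- numeric(n)
    if (t >= 0 && t < eps$stimulus_duration)
      s[1L] <- eps$stimulus_strengths[1]
    if (t >= eps$delay && t < eps$delay + eps$stimulus_duration)
      s[i2] <- eps$stimulus_strengths[2]
    s
  }
}

## default 1 x n observation row for the cascade (last species of pathway 2)
cascade_obs_matrix <- function(spec) {
  function(eps, ti) {
    n <- 2L * spec$n_per_pathway
    resolve_observation(eps, n, default_species = n)
  }
}

## resolve eps$observation into an m x n matrix
resolve_observation <- function(eps, n, default_species) {
  ob <- eps$observation
  if (is.null(ob)) {
    F <- matrix(0, 1, n); F[1, default_species] <- 1
    return(F)
  }
  if (is.list(ob)) {
    F <- matrix(0, 1, n)
    coef <- if (is.null(ob$coef)) 1 else ob$coef
    F[1, ob$species] <- coef
    return(F)
  }
  if (is.matrix(ob)) {
    stopifnot(ncol(ob) == n)
    return(ob)
  }
  matrix(as.numeric(ob), 1, n)
}

#' Build a family of crosstalk cascade models
#'
#' One state-space model per element of `links_per_model`, sharing
#' kinetics, prior, initial state (the unstimulated steady state of the
#' crosstalk-free system at the prior means) and noise specification, and
#' differing only in crosstalk wiring.
#'
#' @param links_per_model List of link lists (each as in [cascade_spec()];
#'   an empty list gives the crosstalk-free model).
#' @param spec Base [cascade_spec()] (its own links must be empty).
#' @param measurement_noise Scalar variance or matrix (default 0.01).
#' @param process_noise_cov Optional `n x n` process-noise covariance.
#' @param names Optional character vector of model names.
#' @param rtol,atol Integrator tolerances.
#' @return List of `utd_ssm` objects.
#' @export
build_crosstalk_family <- function(links_per_model,
                                   spec = cascade_spec(),
                                   measurement_noise = 0.01,
                                   process_noise_cov = NULL,
                                   names = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(spec$crosstalk_links) == 0L)
  n <- 2L * spec$n_per_pathway
  x0 <- cascade_steady_state(spec)
  prior <- cascade_prior(spec)
  if (is.null(names))
    names <- vapply(seq_along(links_per_model), function(i) {
      ll <- links_per_model[[i]]
      if (!length(ll)) "no-crosstalk"
      else paste0("links:", paste(vapply(ll, function(l)
        paste0(l[1], ".", l[2], ">", l[3], ".", l[4]), character(1)),
        collapse = "+"))
    }, character(1))
  if (anyDuplicated(names)) stop("duplicate model link specifications")
  lapply(seq_along(links_per_model), function(i) {
    mspec <- cascade_spec(spec$n_per_pathway, spec$v, spec$lambda, spec$k,
                          spec$n_H, links_per_model[[i]])
    lm <- links_matrix(mspec)
    sim <- function(theta, eps, times) {
      v <- theta[1:n]; lam <- theta[(n + 1):(2 * n)]
      .cascade_integrate_cpp(x0, v, lam, mspec$k, mspec$n_H, lm,
                             eps$stimulus_strengths[1],
                             eps$stimulus_strengths[2], eps$delay,
                             eps$stimulus_duration, 0, times, rtol, atol)
    }
    trans <- function(x, theta, eps, t0, t1) {
      if (t1 == t0) return(x)
      v <- theta[1:n]; lam <- theta[(n + 1):(2 * n)]
      as.numeric(.cascade_integrate_cpp(x, v, lam, mspec$k, mspec$n_H, lm,
                                        eps$stimulus_strengths[1],
                                        eps$stimulus_strengths[2], eps$delay,
                                        eps$stimulus_duration, t0, t1,
                                        rtol, atol))
    }
    state_space_model(
      name = names[i], n_states = n, simulate = sim, state_transition = trans,
      observation_matrix = cascade_obs_matrix(mspec),
      parameter_prior = prior, process_noise_cov = process_noise_cov,
      measurement_noise = measurement_noise, initial_state = x0,
      theta_lower = rep(1e-12, 2 * n))
  })
}

#' All single-link crosstalk models from pathway 1 to pathway 2
#'
#' The 16 models given by every (source index, target index) choice in a
#' 4-species-per-pathway system.
#'
#' @inheritParams build_crosstalk_family
#' @return List of 16 `utd_ssm` objects, ordered source-major
#'   (`1.1>2.1, 1.1>2.2, ..., 1.4>2.4`).
#' @export
build_single_link_family <- function(spec = cascade_spec(),
                                     measurement_noise = 0.01) {
  links <- list()
  for (s in seq_len(spec$n_per_pathway))
    for (tg in seq_len(spec$n_per_pathway))
      links[[length(links) + 1L]] <- list(c(1L, s, 2L, tg))
  build_crosstalk_family(links, spec, measurement_noise = measurement_noise)
}

## ---------------------------------------------------------------------------
## mRNA / protein demonstration model

#' Two-state gene-regulation demonstration model
#'
#' mRNA `m` and protein `p` dynamics
#' `dm/dt = alpha / (1 + R) - delta_m m  (+ stimulus pulse)` and
#' `dp/dt = beta m - delta_p p`, where `R` is the concentration of a
#' repressor protein.  Experiment hooks: `extras$knockout = TRUE` forces
#' the mRNA production term to zero (the stimulus, an external input,
#' is unaffected); `extras$repressor` sets `R` (default 1);
#' `stimulus_strengths[1]` is an additive pulse on the mRNA equation over
#' `[0, stimulus_duration)`.  The observed linear combination of
#' `(m, p)` is an experimental choice via `eps$observation` (default:
#' protein).
#'
#' Theta ordering: `(alpha, delta_m, beta, delta_p)` with independent
#' Gaussian priors `N(1, 0.04)` on the production rates and
#' `N(0.1, 4e-4)` on the degradation rates.
#'
#' @param measurement_noise Scalar variance or matrix (default 0.01).
#' @param initial_state State at time 0 (default `c(0, 0)`).
#' @param rtol,atol Integrator tolerances.
#' @return A `utd_ssm`.
#' @export
build_grn_demo_model <- function(measurement_noise = 0.01,
                                 initial_state = c(0, 0),
                                 rtol = 1e-8, atol = 1e-10) {
  prior <- gaussian_mixture(1, list(gaussian(c(1, 0.1, 1, 0.1),
                                             diag(c(0.04, 4e-4, 0.04, 4e-4)))))
  rhs_for <- function(theta, eps) {
    ko <- isTRUE(eps$extras$knockout)
    R <- if (is.null(eps$extras$repressor)) 1 else eps$extras$repressor
    s1 <- eps$stimulus_strengths[1]
    dur <- eps$stimulus_duration
    function(t, y) {
      production <- if (ko) 0 else theta[1] / (1 + R)
      stim <- if (t >= 0 && t < dur) s1 else 0
      c(production + stim - theta[2] * y[1],
        theta[3] * y[1] - theta[4] * y[2])
    }
  }
  sim <- function(theta, eps, times) {
    ode_rk45(rhs_for(theta, eps), initial_state, times, t_start = 0,
             rtol = rtol, atol = atol,
             breaks = c(0, eps$stimulus_duration))
  }
  trans <- function(x, theta, eps, t0, t1) {
    if (t1 == t0) return(x)
    as.numeric(ode_rk45(rhs_for(theta, eps), x, t1, t_start = t0,
                        rtol = rtol, atol = atol,
                        breaks = c(0, eps$stimulus_duration)))
  }
  state_space_model(
    name = "grn-demo", n_states = 2L, simulate = sim, state_transition = trans,
    observation_matrix = function(eps, ti) resolve_observation(eps, 2L, 2L),
    parameter_prior = prior, measurement_noise = measurement_noise,
    initial_state = initial_state, theta_lower = rep(1e-12, 4))
}

## ---------------------------------------------------------------------------
## Linear-ODE base/extension systems

#' Linear-ODE base model with a hypothesised extension
#'
#' A known `d x d` base Jacobian `A` plus an extension species appended as
#' an extra row `b` and column `cc` (and corner self-term `a_ext`),
#' forming a `(d+1) x (d+1)` Jacobian.  Zero entries of the row/column
#' patterns encode the belief that the corresponding species does not
#' directly interact with the extension and stay zero; `NA` entries are
#' free interaction strengths filled from theta (row entries first, then
#' column entries, in index order).  Additive perturbations `delta` model
#' inaccuracies in the base.
#'
#' @param A `d x d` base Jacobian.
#' @param b_pattern Length-`d` row pattern (numbers fixed, `NA` free).
#' @param c_pattern Length-`d` column pattern (numbers fixed, `NA` free).
#' @param a_ext Self-interaction of the extension species (default -1).
#' @param perturbations List of `list(i =, j =, delta =)` additive
#'   perturbations to base entries.
#' @param prior Optional [gaussian_mixture()] over the free strengths; by
#'   default a mixture fit to the uniform distribution on `[-1, 1]` per
#'   free parameter (see [fit_mixture_to_box()]).
#' @param prior_K,prior_seed Mixture size and seed for the default prior.
#' @return Object of class `utd_linear_spec`.
#' @export
linear_ode_spec <- function(A, b_pattern, c_pattern, a_ext = -1,
                            perturbations = list(), prior = NULL,
                            prior_K = 5L, prior_seed = 1L) {
  A <- as.matrix(A)
  d <- nrow(A)
  stopifnot(ncol(A) == d, length(b_pattern) == d, length(c_pattern) == d)
  n_free <- sum(is.na(b_pattern)) + sum(is.na(c_pattern))
  if (is.null(prior) && n_free > 0)
    prior <- fit_mixture_to_box(rep(-1, n_free), rep(1, n_free), K = prior_K,
                                seed = prior_seed)
  structure(list(A = A, b_pattern = as.numeric(b_pattern),
                 c_pattern = as.numeric(c_pattern), a_ext = a_ext,
                 perturbations = perturbations, prior = prior,
                 n_free = n_free, d = d),
            class = "utd_linear_spec")
}

#' Assemble the perturbed, extended Jacobian
#'
#' @param spec A [linear_ode_spec()].
#' @param theta Free interaction strengths (length `spec$n_free`).
#' @return `(d+1) x (d+1)` Jacobian matrix.
#' @export
assemble_jacobian <- function(spec, theta = numeric()) {
  stopifnot(length(theta) == spec$n_free)
  A <- spec$A
  for (p in spec$perturbations) A[p$i, p$j] <- A[p$i, p$j] + p$delta
  b <- spec$b_pattern; cc <- spec$c_pattern
  idx <- 1L
  for (i in seq_along(b)) if (is.na(b[i])) { b[i] <- theta[idx]; idx <- idx + 1L }
  for (i in seq_along(cc)) if (is.na(cc[i])) { cc[i] <- theta[idx]; idx <- idx + 1L }
  J <- rbind(cbind(A, cc), c(b, spec$a_ext))
  if (any(!is.finite(J))) stop("assemble_jacobian: non-finite entries")
  unname(J)
}

#' Flow of a linear ODE system
#'
#' `x(t) = expm(J t) x0` for the assembled, perturbed, extended Jacobian.
#'
#' @param spec A [linear_ode_spec()].
#' @param x0 Initial state (length `d + 1`).
#' @param t Nonnegative time.
#' @param theta Free interaction strengths.
#' @return State vector at time `t`.
#' @export
linear_ode_transition <- function(spec, x0, t, theta = numeric()) {
  stopifnot(t >= 0)
  J <- assemble_jacobian(spec, theta)
  as.numeric(.expm_cpp(J * t) %*% x0)
}

#' State-space model for a linear-ODE extension hypothesis
#'
#' Wraps a [linear_ode_spec()] as a `utd_ssm` observing the first base
#' variable by default.  Uniformly spaced measurement grids reuse a single
#' matrix exponential per distinct time gap.
#'
#' @param spec A [linear_ode_spec()] with a prior.
#' @param name Model name.
#' @param initial_state Default all-ones (length `d + 1`).
#' @param measurement_noise Scalar variance or matrix (default 0.01).
#' @return A `utd_ssm`.
#' @export
build_linear_extension_model <- function(spec, name = "linear-extension",
                                         initial_state = NULL,
                                         measurement_noise = 0.01) {
  d1 <- spec$d + 1L
  if (is.null(initial_state)) initial_state <- rep(1, d1)
  sim <- function(theta, eps, times) {
    J <- assemble_jacobian(spec, theta)
    gaps <- diff(c(0, times))
    ug <- unique(gaps)
    Es <- lapply(ug, function(g) .expm_cpp(J * g))
    names(Es) <- format(ug, digits = 15)
    out <- matrix(0, length(times), d1)
    x <- initial_state
    for (j in seq_along(times)) {
      x <- as.numeric(Es[[format(gaps[j], digits = 15)]] %*% x)
      out[j, ] <- x
    }
    out
  }
  trans <- function(x, theta, eps, t0, t1) {
    if (t1 == t0) return(x)
    J <- assemble_jacobian(spec, theta)
    as.numeric(.expm_cpp(J * (t1 - t0)) %*% x)
  }
  state_space_model(
    name = name, n_states = d1, simulate = sim, state_transition = trans,
    observation_matrix = function(eps, ti) resolve_observation(eps, d1, 1L),
    parameter_prior = spec$prior, measurement_noise = measurement_noise,
    initial_state = initial_state)
}

## ---------------------------------------------------------------------------
## Synthetic data

#' Observed dataset
#'
#' @param times Strictly increasing measurement times.
#' @param values `T x m` matrix of observations (no missing values).
#' @param observed_map List of the `m x n` observation matrices used at
#'   each time.
#' @return Object of class `utd_dataset`.
#' @export
dataset <- function(times, values, observed_map = NULL) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("dataset: times must be strictly increasing")
  values <- as.matrix(values)
  if (nrow(values) != length(times)) stop("dataset: nrow(values) != length(times)")
  if (anyNA(values)) stop("dataset: missing values not allowed")
  structure(list(times = times, values = values, observed_map = observed_map),
            class = "utd_dataset")
}

## stack a dataset's values time-major into one vector
stack_dataset <- function(D) as.numeric(t(D$values))

#' Simulate a synthetic dataset from a model
#'
#' Integrates `true_model` at `theta_true` under experiment `eps`, applies
#' the observation matrices and adds measurement noise drawn under `seed`.
#' When the model has nonzero process-noise covariance, a Gaussian state
#' perturbation is added after each inter-measurement interval.  The same
#' seed always yields the same dataset.
#'
#' @param true_model A `utd_ssm`.
#' @param theta_true Parameter vector.
#' @param eps An [experiment()].
#' @param seed Integer seed.
#' @return A [dataset()].
#' @export
simulate_dataset <- function(true_model, theta_true, eps, seed = 1L) {
  times <- measurement_times(eps)
  Fs <- lapply(seq_along(times), function(ti)
    true_model$observation_matrix(eps, ti))
  theta <- clip_theta(true_model, theta_true)
  with_seed(seed, {
    Q <- true_model$process_noise_cov
    if (max(abs(Q)) == 0) {
      states <- tryCatch(true_model$simulate(theta, eps, times),
                         error = function(e)
                           stop("integrator failure during simulation: ",
                                conditionMessage(e)))
    } else {
      chQ <- chol(Q + diag(1e-14, nrow(Q)))
      states <- matrix(0, length(times), true_model$n_states)
      x <- true_model$initial_state
      t0 <- 0
      for (j in seq_along(times)) {
        x <- true_model$state_transition(x, theta, eps, t0, times[j])
        x <- x + as.numeric(crossprod(chQ, rnorm(length(x))))
        states[j, ] <- x
        t0 <- times[j]
      }
    }
    values <- t(vapply(seq_along(times), function(ti) {
      Fm <- Fs[[ti]]
      y <- as.numeric(Fm %*% states[ti, ])
      R <- meas_cov(true_model, nrow(Fm))
      if (max(abs(R)) > 0) {
        chR <- chol(R + diag(1e-14, nrow(R)))
        y <- y + as.numeric(crossprod(chR, rnorm(length(y))))
      }
      y
    }, numeric(nrow(Fs[[1]]))))
    if (nrow(Fs[[1]]) == 1L) values <- matrix(values, ncol = 1L)
    dataset(times, values, Fs)
  })
}
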