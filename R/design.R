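## Experiment scoring and optimisation: Hellinger distances between prior
## predictive distributions, the sum-of-exponentials multi-model cost, and
## a seeded real-coded genetic algorithm over experiment parameters.

#' Hellinger distance between two multivariate Gaussians
#'
#' Closed form: with `S = (Sigma1 + Sigma2) / 2`,
#' `H^2 = 1 - det(Sigma1)^(1/4) det(Sigma2)^(1/4) / det(S)^(1/2) *
#' exp(-(1/8) (mu1-mu2)' S^{-1} (mu1-mu2))`.  Computed with log
#' determinants via Cholesky for stability.
#'
#' @param g1,g2 [gaussian()] objects of equal dimension.
#' @return Hellinger distance in `[0, 1]`.
#' @examples
#' hellinger_gaussian(gaussian(0, 1), gaussian(1, 1))  # sqrt(1 - exp(-1/8))
#' @export
hellinger_gaussian <- function(g1, g2) {
  d <- length(g1$mean)
  if (length(g2$mean) != d) stop("hellinger_gaussian: dimension mismatch")
  S <- (g1$cov + g2$cov) / 2
  ch <- tryCatch(chol(S), error = function(e)
    stop("hellinger_gaussian: singular average covariance"))
  ld_S <- 2 * sum(log(diag(ch)))
  ld1 <- tryCatch(2 * sum(log(diag(chol(g1$cov + diag(1e-300, d))))),
                  error = function(e) -Inf)
  ld2 <- tryCatch(2 * sum(log(diag(chol(g2$cov + diag(1e-300, d))))),
                  error = function(e) -Inf)
  z <- backsolve(ch, g1$mean - g2$mean, transpose = TRUE)
  log_bc <- 0.25 * ld1 + 0.25 * ld2 - 0.5 * ld_S - sum(z^2) / 8
  h2 <- 1 - exp(log_bc)
  sqrt(min(1, max(0, h2)))
}

#' Hellinger distance between two Gaussian mixtures
#'
#' When both mixtures have a single component the closed form
#' [hellinger_gaussian()] is used.  Otherwise the Bhattacharyya integral
#' `BC = int sqrt(p q)` is estimated by seeded importance sampling with
#' the equal-weight pooled mixture `(p + q) / 2` as proposal, and
#' `H = sqrt(1 - BC)` clipped to `[0, 1]`.
#'
#' @param m1,m2 [gaussian_mixture()] (or [gaussian()]) of equal dimension.
#' @param method `"auto"` (dispatch as above), `"closed_form"` (requires
#'   single components) or `"importance"`.
#' @param n_samples Importance-sample size (default `1e4`).
#' @param seed Integer seed for the sampler.
#' @return Hellinger distance in `[0, 1]`.
#' @export
hellinger_mixture <- function(m1, m2, method = "auto", n_samples = 10000L,
                              seed = 1L) {
  if (inherits(m1, "utd_gaussian")) m1 <- gaussian_mixture(1, list(m1))
  if (inherits(m2, "utd_gaussian")) m2 <- gaussian_mixture(1, list(m2))
  single <- n_components(m1) == 1L && n_components(m2) == 1L
  method <- match.arg(method, c("auto", "closed_form", "importance"))
  if (method == "closed_form" && !single)
    stop("closed_form requires single-component mixtures")
  if (method == "auto" && single) method <- "closed_form"
  if (method == "closed_form" ||
      (method == "auto" && single))
    return(hellinger_gaussian(m1$components[[1]], m2$components[[1]]))
  ## pooled-proposal importance sampling
  prop <- gaussian_mixture(c(m1$weights / 2, m2$weights / 2),
                           c(m1$components, m2$components))
  with_seed(seed, {
    X <- rmixture(n_samples, prop)
    lw <- vapply(seq_len(n_samples), function(i) {
      x <- X[i, ]
      0.5 * (dmixture_log(x, m1) + dmixture_log(x, m2)) - dmixture_log(x, prop)
    }, numeric(1))
    bc <- exp(lse(lw) - log(n_samples))
    sqrt(min(1, max(0, 1 - bc)))
  })
}

#' Pairwise Hellinger distances between model prior predictives
#'
#' Entry `(i, j)` is the Hellinger distance between the prior predictive
#' distributions of models `i` and `j` under experiment `eps`; the
#' diagonal is zero.
#'
#' @param models List of `utd_ssm` sharing an observation space under
#'   `eps`.
#' @param eps An [experiment()].
#' @param params [ut_params()].
#' @param seed Seed for the mixture Hellinger estimator (multi-component
#'   priors only).
#' @param predictives Optional precomputed list of `utd_predictive`.
#' @return Symmetric matrix with model names on the dimnames.
#' @export
pairwise_scores <- function(models, eps, params = ut_params(), seed = 1L,
                            predictives = NULL) {
  if (length(models) < 2) stop("pairwise_scores: need at least two models")
  if (is.null(predictives))
    predictives <- lapply(models, prior_predictive_stochastic, eps = eps,
                          params = params)
  M <- length(predictives)
  H <- matrix(0, M, M)
  for (i in seq_len(M - 1)) for (j in (i + 1):M) {
    H[i, j] <- H[j, i] <- hellinger_mixture(predictives[[i]]$mixture,
                                            predictives[[j]]$mixture,
                                            seed = seed)
  }
  nm <- vapply(predictives, `[[`, character(1), "model_name")
  dimnames(H) <- list(nm, nm)
  H
}

#' Multi-model design cost
#'
#' `sum_{i<j} exp(gamma * H_ij)`: the exponential rewards experiments that
#' separate at least some model pairs decisively over experiments with a
#' mediocre average separation.  For two models it is strictly increasing
#' in the single pairwise distance.
#'
#' @param H Symmetric pairwise Hellinger matrix.
#' @param gamma Exponent scale (default 10).
#' @return Scalar cost (to be maximised).
#' @export
design_cost <- function(H, gamma = 10) {
  sum(exp(gamma * H[upper.tri(H)]))
}

#' Bounds and fixed structure of the experiment search space
#'
#' Continuous design coordinates are any subset of `s1`, `s2`, `delay`,
#' `t_obs`, `spacing` with per-coordinate lower/upper bounds; the observed
#' species may optionally be a categorical gene over `species_choices`.
#' All remaining experiment fields are taken from `fixed`.
#'
#' @param lower,upper Named numeric vectors (equal names, `lower <=
#'   upper`).
#' @param species_choices Optional integer vector of observable-species
#'   choices (categorical gene).
#' @param fixed Named list of fixed [experiment()] arguments.
#' @return Object of class `utd_bounds`.
#' @export
experiment_bounds <- function(lower, upper, species_choices = NULL,
                              fixed = list()) {
  stopifnot(length(lower) > 0, identical(names(lower), names(upper)),
            all(lower <= upper))
  ok <- c("s1", "s2", "delay", "t_obs", "spacing")
  if (!all(names(lower) %in% ok))
    stop("experiment_bounds: unknown coordinates ",
         paste(setdiff(names(lower), ok), collapse = ", "))
  structure(list(lower = lower, upper = upper,
                 species_choices = species_choices, fixed = fixed),
            class = "utd_bounds")
}

## decode a genome (continuous vector + optional categorical) into an
## experiment
decode_experiment <- function(bounds, x, species = NULL) {
  g <- as.list(x)
  names(g) <- names(bounds$lower)
  args <- list(
    stimulus_strengths = c(if (!is.null(g$s1)) g$s1 else 0,
                           if (!is.null(g$s2)) g$s2 else 0),
    delay = if (!is.null(g$delay)) g$delay else 0,
    t_obs = if (!is.null(g$t_obs)) max(g$t_obs, 1e-6) else 1,
    spacing = if (!is.null(g$spacing)) g$spacing else 1)
  args <- modifyList(args, bounds$fixed)
  if (!is.null(species)) args$observation <- list(species = species, coef = 1)
  do.call(experiment, args)
}

#' Draw an experiment uniformly from bounds
#'
#' @param bounds An [experiment_bounds()].
#' @return An [experiment()] (uses the current RNG state).
#' @export
random_experiment <- function(bounds) {
  x <- runif(length(bounds$lower), bounds$lower, bounds$upper)
  sp <- if (!is.null(bounds$species_choices))
    sample(bounds$species_choices, 1) else NULL
  decode_experiment(bounds, x, sp)
}

#' Genetic-algorithm configuration
#'
#' Small, reproducible defaults: tournament selection (size 3), blend
#' crossover (rate 0.7), per-gene Gaussian mutation with standard
#' deviation 5% of the bound range, single-elite survival.
#'
#' @param population,generations GA size.
#' @param crossover_rate,mutation_rate Per-pair / per-gene probabilities.
#' @param mutation_sd_frac Mutation SD as a fraction of each bound range.
#' @param tournament Tournament size.
#' @param elitism Number of elites carried over unchanged.
#' @param gamma [design_cost()] exponent scale.
#' @return List of class `utd_ga_config`.
#' @export
ga_config <- function(population = 100L, generations = 50L,
                      crossover_rate = 0.7, mutation_rate = 0.2,
                      mutation_sd_frac = 0.05, tournament = 3L, elitism = 1L,
                      gamma = 10) {
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sd_frac = mutation_sd_frac,
                 tournament = as.integer(tournament),
                 elitism = as.integer(elitism), gamma = gamma),
            class = "utd_ga_config")
}

#' Optimise an experiment by a seeded genetic algorithm
#'
#' Maximises [design_cost()] of the pairwise Hellinger matrix over the
#' experiment parameters.  Real-coded GA with tournament selection, blend
#' (BLX-0.5) crossover clipped to bounds, Gaussian mutation, uniform-reset
#' mutation for the categorical observed-species gene, and elitism (the
#' best-score trace is therefore nondecreasing).  Fully reproducible given
#' `seed`.
#'
#' @param models List of `utd_ssm` (>= 2).
#' @param bounds An [experiment_bounds()].
#' @param config A [ga_config()].
#' @param seed Integer seed.
#' @param params [ut_params()].
#' @param score_fn Optional replacement score `function(eps) -> scalar`
#'   (then `pairwise_hellinger` of the result is computed at the optimum
#'   only).
#' @return Object of class `utd_design_result`: `best_eps`, `score`,
#'   `pairwise_hellinger`, `ga_trace`, `seed`.
#' @export
optimize_experiment <- function(models, bounds, config = ga_config(),
                                seed = 1L, params = ut_params(),
                                score_fn = NULL) {
  nc <- length(bounds$lower)
  has_cat <- !is.null(bounds$species_choices)
  rng <- bounds$upper - bounds$lower
  eval_eps <- function(x, sp) {
    eps <- decode_experiment(bounds, x, sp)
    if (!is.null(score_fn)) return(score_fn(eps))
    H <- pairwise_scores(models, eps, params = params, seed = seed)
    design_cost(H, gamma = config$gamma)
  }
  with_seed(seed, {
    P <- config$population
    X <- matrix(runif(P * nc, rep(bounds$lower, each = P),
                      rep(bounds$upper, each = P)), P, nc)
    SP <- if (has_cat) sample(bounds$species_choices, P, replace = TRUE)
          else rep(NA_integer_, P)
    fit <- vapply(seq_len(P), function(i)
      eval_eps(X[i, ], if (has_cat) SP[i] else NULL), numeric(1))
    trace <- numeric(config$generations + 1)
    trace[1] <- max(fit)
    for (gen in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      Xn <- X; SPn <- SP
      ne <- min(config$elitism, P)
      if (ne > 0) {
        Xn[seq_len(ne), ] <- X[ord[seq_len(ne)], , drop = FALSE]
        SPn[seq_len(ne)] <- SP[ord[seq_len(ne)]]
      }
      tourn <- function() {
        cand <- sample.int(P, config$tournament, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      for (i in seq(ne + 1, P)) {
        p1 <- tourn(); p2 <- tourn()
        child <- X[p1, ]; sp <- SP[p1]
        if (runif(1) < config$crossover_rate) {
          a <- runif(nc, -0.5, 1.5)         # BLX-0.5 per gene
          child <- X[p1, ] + a * (X[p2, ] - X[p1, ])
          if (has_cat && runif(1) < 0.5) sp <- SP[p2]
        }
        mut <- runif(nc) < config$mutation_rate
        child[mut] <- child[mut] + rnorm(sum(mut), 0,
                                         config$mutation_sd_frac * rng[mut])
        child <- pmin(pmax(child, bounds$lower), bounds$upper)
        if (has_cat && runif(1) < config$mutation_rate)
          sp <- sample(bounds$species_choices, 1)
        Xn[i, ] <- child; SPn[i] <- sp
      }
      X <- Xn; SP <- SPn
      fit <- vapply(seq_len(P), function(i)
        eval_eps(X[i, ], if (has_cat) SP[i] else NULL), numeric(1))
      ## elites guarantee monotone best-score trace
      trace[gen + 1] <- max(trace[gen], max(fit))
    }
    best <- which.max(fit)
    best_eps <- decode_experiment(bounds, X[best, ],
                                  if (has_cat) SP[best] else NULL)
    H <- if (is.null(score_fn))
      pairwise_scores(models, best_eps, params = params, seed = seed)
    else matrix(NA_real_, length(models), length(models))
    structure(list(best_eps = best_eps, score = max(fit[best], trace[length(trace)]),
                   pairwise_hellinger = H, ga_trace = trace, seed = seed),
              class = "utd_design_result")
  })
}

#' @export
print.utd_design_result <- function(x, ...) {
  cat("Design result: score", format(x$score, digits = 5), "\n")
  cat("  best experiment: s =", format(x$best_eps$stimulus_strengths, digits = 3),
      " delay =", format(x$best_eps$delay, digits = 3),
      " t_obs =", format(x$best_eps$t_obs, digits = 3), "\n")
  invisible(x)
}
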