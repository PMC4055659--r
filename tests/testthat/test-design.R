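test_that("closed-form Hellinger distances match known values and axioms", {
  g <- gaussian(0.3, 1.7)
  expect_equal(hellinger_gaussian(g, g), 0)
  expect_equal(hellinger_gaussian(gaussian(0, 1), gaussian(1, 1)),
               sqrt(1 - exp(-1 / 8)), tolerance = 1e-12)
  # symmetric, bounded, and -> 1 as the means separate
  a <- gaussian(c(0, 0), diag(2)); b <- gaussian(c(2, -1), diag(c(0.5, 3)))
  expect_equal(hellinger_gaussian(a, b), hellinger_gaussian(b, a),
               tolerance = 1e-12)
  expect_gt(hellinger_gaussian(gaussian(100, 1), gaussian(0, 1)), 1 - 1e-12)
  expect_error(hellinger_gaussian(a, gaussian(0, 1)), "dimension")
  expect_error(hellinger_gaussian(gaussian(0, 0), gaussian(0, 0)), "singular")
})

test_that("the closed form agrees with quadrature on 100 random 1-D pairs", {
  set.seed(14)
  for (i in 1:100) {
    m1 <- rnorm(1, 0, 2); m2 <- rnorm(1, 0, 2)
    s1 <- runif(1, 0.3, 2); s2 <- runif(1, 0.3, 2)
    h_cf <- hellinger_gaussian(gaussian(m1, s1^2), gaussian(m2, s2^2))
    h_q <- hellinger_quadrature_1d(function(x) dnorm(x, m1, s1),
                                   function(x) dnorm(x, m2, s2),
                                   min(m1, m2) - 8 * max(s1, s2),
                                   max(m1, m2) + 8 * max(s1, s2))
    expect_equal(h_cf, h_q, tolerance = 1e-6)
  }
})

test_that("mixture Hellinger dispatches, self-distances vanish, and the
           sampler tracks quadrature", {
  g1 <- gaussian(0, 1); g2 <- gaussian(1.5, 0.6)
  expect_identical(hellinger_mixture(g1, g2), hellinger_gaussian(g1, g2))
  expect_error(hellinger_mixture(g1, g2, method = "nope"))

  m <- gaussian_mixture(c(0.4, 0.6), list(gaussian(-2, 0.5), gaussian(2, 1)))
  expect_lte(hellinger_mixture(m, m, seed = 2), 0.02)
  expect_error(hellinger_mixture(m, m, method = "closed_form"),
               "single-component")

  m1 <- gaussian_mixture(c(0.5, 0.5), list(gaussian(-3, 0.4), gaussian(0, 0.4)))
  m2 <- gaussian_mixture(c(0.3, 0.7), list(gaussian(2, 0.6), gaussian(5, 0.8)))
  h_is <- hellinger_mixture(m1, m2, n_samples = 20000L, seed = 5)
  h_q <- hellinger_quadrature_1d(function(x) exp(vapply(x, dmixture_log, numeric(1), m = m1)),
                                 function(x) exp(vapply(x, dmixture_log, numeric(1), m = m2)),
                                 -10, 12)
  expect_equal(h_is, h_q, tolerance = 0.01)

  # seeded estimates are reproducible
  expect_identical(h_is, hellinger_mixture(m1, m2, n_samples = 20000L, seed = 5))
})

test_that("pairwise score matrices are symmetric with zero diagonal", {
  fam <- six_models()[c(1, 4)]
  eps <- experiment(stimulus_strengths = c(5, 5), t_obs = 8)
  H <- pairwise_scores(fam, eps)
  expect_equal(H, t(H))
  expect_equal(diag(H), c(0, 0), ignore_attr = TRUE)

  # two copies of the same model score zero everywhere
  H0 <- pairwise_scores(list(fam[[1]], fam[[1]]), eps)
  expect_equal(max(abs(H0)), 0, tolerance = 1e-9)
  expect_error(pairwise_scores(fam[1], eps), "two models")

  # an uninformative (very early) measurement separates less than a
  # designed one
  H_early <- pairwise_scores(six_models(), experiment(
    stimulus_strengths = c(5, 5), t_obs = 0.05))
  H_good <- pairwise_scores(six_models(), separating_experiment())
  expect_true(all(H_early[upper.tri(H_early)] < H_good[upper.tri(H_good)]))
  expect_lt(max(H_early), 0.1)
})

test_that("the design cost is a monotone sum of exponentials", {
  H0 <- matrix(0, 4, 4)
  expect_equal(design_cost(H0), 6)          # M(M-1)/2 pairs at e^0
  H1 <- H0; H1[1, 2] <- H1[2, 1] <- 0.5
  expect_gt(design_cost(H1), design_cost(H0))
  H2 <- H1; H2[3, 4] <- H2[4, 3] <- 0.2
  expect_gt(design_cost(H2), design_cost(H1))
  # componentwise-ordered matrices give ordered costs
  expect_gt(design_cost(H2 * 1.5), design_cost(H2))
  # gamma controls the exponent scale
  expect_equal(design_cost(H1, gamma = 0), 6)
})

test_that("experiment bounds validate and decode", {
  expect_error(experiment_bounds(c(zz = 0), c(zz = 1)), "unknown")
  expect_error(experiment_bounds(c(s1 = 1), c(s1 = 0)))
  b <- experiment_bounds(c(s1 = 0, t_obs = 1), c(s1 = 5, t_obs = 50),
                         fixed = list(n_timepoints = 3L, spacing = 2))
  set.seed(1)
  eps <- random_experiment(b)
  expect_s3_class(eps, "utd_experiment")
  expect_true(eps$stimulus_strengths[1] >= 0 && eps$stimulus_strengths[1] <= 5)
  expect_identical(eps$n_timepoints, 3L)
})

test_that("the GA maximises, is elitist and seed-reproducible", {
  # toy pair of 1-state models whose predictives separate only for
  # t_obs in (3, 5): a transient bump on one of them
  bump_model <- function(name, has_bump) {
    sim <- function(theta, eps, times) {
      y <- theta[1] * exp(-0.1 * times)
      if (has_bump) y <- y + 2 * exp(-((times - 4)^2) / 0.35)
      matrix(y, ncol = 1)
    }
    state_space_model(
      name = name, n_states = 1, simulate = sim,
      state_transition = function(x, theta, eps, t0, t1) x,
      observation_matrix = function(eps, ti) matrix(1, 1, 1),
      parameter_prior = gaussian(1, 0.01), measurement_noise = 0.01,
      initial_state = 1)
  }
  models <- list(bump_model("flat", FALSE), bump_model("bumped", TRUE))
  bounds <- experiment_bounds(c(t_obs = 0.5), c(t_obs = 10),
                              fixed = list(n_timepoints = 1L))

  # exhaustive grid oracle at resolution 0.01
  grid <- seq(0.5, 10, by = 0.01)
  gscore <- vapply(grid, function(tb) {
    H <- pairwise_scores(models, experiment(t_obs = tb))
    design_cost(H)
  }, numeric(1))
  window <- range(grid[gscore > 0.95 * max(gscore)])

  res <- optimize_experiment(models, bounds,
                             config = ga_config(population = 16,
                                                generations = 12),
                             seed = 3)
  expect_gte(res$best_eps$t_obs, 3)
  expect_lte(res$best_eps$t_obs, 5)
  expect_gte(res$score, max(gscore) * 0.99)
  expect_true(res$best_eps$t_obs >= window[1] - 0.2 &&
              res$best_eps$t_obs <= window[2] + 0.2)

  # elitism: the trace is nondecreasing and ends at the reported score
  expect_true(all(diff(res$ga_trace) >= 0))
  expect_gte(res$score, res$ga_trace[1])
  expect_equal(res$score, res$ga_trace[length(res$ga_trace)])
  expect_equal(res$score, design_cost(res$pairwise_hellinger))

  res2 <- optimize_experiment(models, bounds,
                              config = ga_config(population = 16,
                                                 generations = 12),
                              seed = 3)
  expect_identical(res, res2)
})

test_that("categorical observed-species genes are searched too", {
  fam <- six_models()[c(1, 6)]
  bounds <- experiment_bounds(c(s1 = 0, t_obs = 1), c(s1 = 5, t_obs = 40),
                              species_choices = 5:8,
                              fixed = list(n_timepoints = 1L))
  res <- optimize_experiment(fam, bounds,
                             config = ga_config(population = 10,
                                                generations = 5),
                             seed = 2)
  expect_true(res$best_eps$observation$species %in% 5:8)
  expect_true(all(diff(res$ga_trace) >= 0))
})
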