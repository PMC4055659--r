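test_that("UT predictives are exact for models affine in theta", {
  mod <- affine_ssm()
  eps <- experiment(t_obs = 1, n_timepoints = 3, spacing = 1)
  pred <- prior_predictive_deterministic(mod, eps, ut_params(alpha = 1))

  M <- rbind(c(1, 0.5), c(-0.3, 2)); b <- c(0.2, -0.1)
  g0 <- mod$parameter_prior$components[[1]]
  Mfull <- do.call(rbind, lapply(1:3, function(t) t * M))
  bfull <- unlist(lapply(1:3, function(t) t * b))
  mu <- as.numeric(Mfull %*% g0$mean + bfull)
  S <- Mfull %*% g0$cov %*% t(Mfull) + diag(0.04, 6)
  expect_equal(pred$mixture$components[[1]]$mean, mu, tolerance = 1e-8)
  expect_equal(pred$mixture$components[[1]]$cov, S, tolerance = 1e-8)
})

test_that("a near-point prior collapses the predictive onto one trajectory", {
  mod <- six_models()[[4]]
  th <- mod$parameter_prior$components[[1]]$mean
  mod$parameter_prior <- gaussian_mixture(1, list(gaussian(th,
    diag(1e-16, length(th)))))
  eps <- experiment(stimulus_strengths = c(5, 5), t_obs = 5,
                    n_timepoints = 3, spacing = 5)
  pred <- prior_predictive_deterministic(mod, eps)
  states <- mod$simulate(th, eps, measurement_times(eps))
  expect_equal(pred$mixture$components[[1]]$mean, states[, 8],
               tolerance = 1e-6)
})

test_that("log marginal likelihood evaluates the mixture density stably", {
  D0 <- dataset(1, matrix(0, 1, 1))
  p <- gaussian_mixture(1, list(gaussian(0, 1)))
  expect_equal(log_marginal_likelihood(p, D0), log(1 / sqrt(2 * pi)),
               tolerance = 1e-9)

  # duplicated components collapse
  p2 <- gaussian_mixture(c(0.5, 0.5), list(gaussian(0, 1), gaussian(0, 1)))
  expect_equal(log_marginal_likelihood(p2, D0),
               log_marginal_likelihood(p, D0), tolerance = 1e-12)

  expect_error(log_marginal_likelihood(p, dataset(1:2, matrix(0, 2, 1))),
               "dimension")

  # mixture evidence equals the weight-sum of componentwise evidences
  mix <- gaussian_mixture(c(0.3, 0.7), list(gaussian(0, 1), gaussian(2, 3)))
  lev <- log_marginal_likelihood(mix, D0)
  parts <- vapply(mix$components, function(g)
    log_marginal_likelihood(gaussian_mixture(1, list(g)), D0), numeric(1))
  expect_equal(lev, utdesign:::lse(log(mix$weights) + parts),
               tolerance = 1e-12)
})

test_that("UT evidence matches the conjugate closed form for affine models", {
  mod <- affine_ssm()
  eps <- experiment(t_obs = 1, n_timepoints = 3, spacing = 1)
  D <- simulate_dataset(mod, c(1.2, -0.8), eps, seed = 2)
  lev <- log_marginal_likelihood(
    prior_predictive_deterministic(mod, eps, ut_params(alpha = 1)), D)
  expect_equal(lev, affine_evidence(mod, eps, D), tolerance = 1e-6)
})

test_that("Gaussian evidence obeys the probability chain rule on nested data", {
  mod <- affine_ssm()
  eps2 <- experiment(t_obs = 1, n_timepoints = 2, spacing = 1)
  D2 <- simulate_dataset(mod, c(0.9, -1.1), eps2, seed = 6)
  pred2 <- prior_predictive_deterministic(mod, eps2, ut_params(alpha = 1))
  g <- pred2$mixture$components[[1]]

  idxA <- 1:2                      # first time point (m = 2 observables)
  idxB <- 3:4
  y <- utdesign:::stack_dataset(D2)
  lev_joint <- log_marginal_likelihood(pred2, D2)
  lev_A <- utdesign:::dgauss_log(y[idxA],
                                 gaussian(g$mean[idxA],
                                          g$cov[idxA, idxA, drop = FALSE]))
  # conditional Gaussian of block B given block A
  SAB <- g$cov[idxA, idxB]
  SAA <- g$cov[idxA, idxA]
  mu_c <- g$mean[idxB] + t(SAB) %*% solve(SAA, y[idxA] - g$mean[idxA])
  S_c <- g$cov[idxB, idxB] - t(SAB) %*% solve(SAA, SAB)
  lev_B <- utdesign:::dgauss_log(y[idxB], gaussian(as.numeric(mu_c), S_c))
  expect_equal(lev_joint, lev_A + lev_B, tolerance = 1e-8)
})

test_that("the MC oracle agrees with the conjugate evidence and scales with n", {
  mod <- affine_ssm()
  eps <- experiment(t_obs = 1, n_timepoints = 3, spacing = 1)
  D <- simulate_dataset(mod, c(1.2, -0.8), eps, seed = 2)
  mc <- mc_log_marginal_likelihood(mod, eps, D, n_samples = 10000L, seed = 4)
  expect_lt(abs(mc$estimate - affine_evidence(mod, eps, D)), 3 * mc$se)

  # reproducibility
  mc2 <- mc_log_marginal_likelihood(mod, eps, D, n_samples = 10000L, seed = 4)
  expect_identical(mc, mc2)

  # SE shrinks like 1/sqrt(n) on average over seeds
  r <- vapply(1:6, function(s) {
    a <- mc_log_marginal_likelihood(mod, eps, D, n_samples = 1000L, seed = s)
    b <- mc_log_marginal_likelihood(mod, eps, D, n_samples = 2000L, seed = s)
    b$se / a$se
  }, numeric(1))
  expect_equal(mean(r), 1 / sqrt(2), tolerance = 0.15)

  expect_error(mc_log_marginal_likelihood(mod, eps, D, n_samples = 10),
               "n_samples")
})

test_that("the stochastic joint matches the Kalman prediction closed form", {
  A <- matrix(c(0.9, 0.2, 0, 0.7), 2, 2)
  Q <- diag(c(0.05, 0.02)); R <- 0.01
  Fm <- matrix(c(1, 0), 1, 2); x0 <- c(1, -0.5)
  mod <- kalman_ssm(A, Q, R, Fm, x0)
  eps <- experiment(t_obs = 1, n_timepoints = 4, spacing = 1)
  pred <- prior_predictive_stochastic(mod, eps, ut_params(alpha = 1))
  oracle <- kalman_prediction_moments(A, Q, R, Fm, x0, 4)
  g <- pred$mixture$components[[1]]
  expect_equal(g$mean, oracle$mean, tolerance = 1e-8)
  expect_equal(g$cov, oracle$cov, tolerance = 1e-8)
  # symmetric PSD output
  expect_equal(g$cov, t(g$cov))
  expect_gte(min(eigen(g$cov, symmetric = TRUE)$values), 0)
})

test_that("zero process noise dispatches to the deterministic construction", {
  for (mod in list(six_models()[[2]], build_grn_demo_model())) {
    eps <- experiment(stimulus_strengths = c(4, 1), t_obs = 4,
                      n_timepoints = 3, spacing = 4)
    p_det <- prior_predictive_deterministic(mod, eps)
    p_sto <- prior_predictive_stochastic(mod, eps)
    expect_equal(p_sto$mixture, p_det$mixture, tolerance = 1e-12)
    th <- mod$parameter_prior$components[[1]]$mean
    D <- simulate_dataset(mod, th, eps, seed = 9)
    expect_equal(log_marginal_likelihood(p_sto, D),
                 log_marginal_likelihood(p_det, D), tolerance = 1e-6)
  }
})

test_that("the stochastic construction is continuous in small process noise", {
  grn <- build_grn_demo_model()
  eps <- experiment(stimulus_strengths = c(2, 0), t_obs = 2,
                    n_timepoints = 5, spacing = 2)
  p0 <- prior_predictive_deterministic(grn, eps)
  grn$process_noise_cov <- diag(1e-12, 2)
  p1 <- prior_predictive_stochastic(grn, eps)
  g0 <- p0$mixture$components[[1]]; g1 <- p1$mixture$components[[1]]
  # iterated and direct UT differ beyond second order; agreement is
  # relative, not exact
  expect_equal(g1$mean, g0$mean, tolerance = 1e-3)
  expect_lt(max(abs(g1$cov - g0$cov)) / max(abs(g0$cov)), 0.01)
})

test_that("predictive marginalisation equals recomputation on the sub-schedule", {
  mod <- six_models()[[3]]
  eps8 <- experiment(stimulus_strengths = c(5, 5), delay = 10, t_obs = 3,
                     n_timepoints = 8, spacing = 3)
  full <- prior_predictive_deterministic(mod, eps8)
  idx <- 1:4
  sub <- marginalize_predictive(full, idx)
  eps4 <- experiment(stimulus_strengths = c(5, 5), delay = 10, t_obs = 3,
                     n_timepoints = 4, spacing = 3)
  direct <- prior_predictive_deterministic(mod, eps4)
  expect_equal(sub$mixture$components[[1]]$mean,
               direct$mixture$components[[1]]$mean, tolerance = 1e-9)
  expect_equal(sub$mixture$components[[1]]$cov,
               direct$mixture$components[[1]]$cov, tolerance = 1e-8)
  expect_equal(sub$times, measurement_times(eps4))
})
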