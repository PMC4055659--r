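test_that("cascade_spec validates rates, links and the Hill coefficient", {
  expect_error(cascade_spec(v = -1), "positive")
  expect_error(cascade_spec(lambda = 0), "positive")
  expect_error(cascade_spec(n_H = 0.5), "n_H")
  expect_error(cascade_spec(crosstalk_links = list(c(1, 5, 2, 1))),
               "out of range")
  expect_error(cascade_spec(crosstalk_links = list(c(1, 2, 2, 3),
                                                   c(1, 2, 2, 3))),
               "duplicate")
})

test_that("the Hill function is half-maximal at u = k", {
  expect_equal(hill(10, 10, 2), 0.5)
  expect_equal(hill(3, 3, 7), 0.5)
  expect_equal(hill(0, 1, 2), 0)
  expect_equal(hill(-1, 1, 2), 0)  # clipped below zero
  expect_lt(hill(1e6, 1, 2), 1)
})

test_that("cascade_rhs computes production, decay and stimulus terms", {
  spec <- cascade_spec()
  # at zero state with no stimulus only constitutive production remains
  dy <- cascade_rhs(rep(0, 8), spec)
  expect_equal(dy[c(1, 5)], spec$v[c(1, 5)])
  expect_equal(dy[-c(1, 5)], rep(0, 6))

  # derivative vanishes at the closed-form steady state
  ss <- cascade_steady_state(spec)
  expect_equal(cascade_rhs(ss, spec), rep(0, 8), tolerance = 1e-12)

  # additive stimulus passes straight through
  stim <- function(t) c(3, rep(0, 7))
  expect_equal(cascade_rhs(ss, spec, stim, 0)[1], 3, tolerance = 1e-12)

  # a crosstalk link adds an activating Hill production term
  spec2 <- cascade_spec(crosstalk_links = list(c(1, 2, 2, 3)))
  d2 <- cascade_rhs(ss, spec2)
  extra <- spec2$v[7] * hill(ss[2], spec2$k[7], spec2$n_H)
  expect_equal(d2[7], extra, tolerance = 1e-12)
  expect_equal(d2[-7], rep(0, 7), tolerance = 1e-12)

  expect_error(cascade_rhs(rep(0, 5), spec), "length")
})

test_that("a 2-species chain settles at the fixed point of its kinetics", {
  spec <- cascade_spec(n_per_pathway = 2L)
  # long integration from an arbitrary state (independent oracle for the
  # closed-form steady state)
  y <- ode_rk45(function(t, y) cascade_rhs(y, spec), rep(0.5, 4), 400,
                rtol = 1e-10, atol = 1e-12)
  x <- y[1, ]
  expect_equal(spec$v[2] * hill(x[1], spec$k[2], spec$n_H),
               spec$lambda[2] * x[2], tolerance = 1e-6)
  expect_equal(x, cascade_steady_state(spec), tolerance = 1e-6)
})

test_that("compiled and R-level cascade dynamics agree", {
  spec <- cascade_spec(crosstalk_links = list(c(1, 2, 2, 3)))
  eps <- experiment(stimulus_strengths = c(3, 2), delay = 4, t_obs = 10,
                    n_timepoints = 3, spacing = 5)
  ss <- cascade_steady_state(spec)
  stim <- utdesign:::cascade_stimulus(spec, eps)
  yr <- ode_rk45(function(t, y) cascade_rhs(y, spec, stim, t), ss,
                 measurement_times(eps), breaks = c(0, 5, 4, 9))
  yc <- utdesign:::.cascade_integrate_cpp(
    ss, spec$v, spec$lambda, spec$k, spec$n_H,
    utdesign:::links_matrix(spec), 3, 2, 4, 5, 0,
    measurement_times(eps), 1e-8, 1e-10)
  expect_equal(yr, yc, tolerance = 1e-7)
})

test_that("crosstalk families share everything except wiring", {
  fam <- build_single_link_family()
  expect_length(fam, 16L)
  expect_equal(anyDuplicated(vapply(fam, `[[`, character(1), "name")), 0L)
  expect_error(build_crosstalk_family(list(list(), list())), "duplicate")

  eps <- experiment(stimulus_strengths = c(4, 0), t_obs = 5,
                    n_timepoints = 4, spacing = 5)
  th <- fam[[1]]$parameter_prior$components[[1]]$mean

  # two models with identical links simulate identically
  fam2 <- build_crosstalk_family(list(list(c(1, 2, 2, 3))), names = "copy")
  orig <- build_crosstalk_family(list(list(c(1, 2, 2, 3))))
  expect_equal(fam2[[1]]$simulate(th, eps, 1:5), orig[[1]]$simulate(th, eps, 1:5))

  # without crosstalk, pathway 2 is invariant to the pathway-1 stimulus
  none <- build_crosstalk_family(list(list()))[[1]]
  eps_a <- experiment(stimulus_strengths = c(0, 2), delay = 3, t_obs = 5,
                      n_timepoints = 4, spacing = 5)
  eps_b <- experiment(stimulus_strengths = c(5, 2), delay = 3, t_obs = 5,
                      n_timepoints = 4, spacing = 5)
  sa <- none$simulate(th, eps_a, 2:6)
  sb <- none$simulate(th, eps_b, 2:6)
  expect_equal(sa[, 5:8], sb[, 5:8], tolerance = 1e-9)
  expect_gt(max(abs(sa[, 1] - sb[, 1])), 0.1)
})

test_that("cascade trajectories stay nonnegative from nonnegative starts", {
  fam <- six_models()
  set.seed(21)
  for (rep in 1:5) {
    mod <- fam[[sample.int(6, 1)]]
    theta <- pmax(rmixture(1, mod$parameter_prior)[1, ], 1e-12)
    eps <- experiment(stimulus_strengths = runif(2, 0, 5),
                      delay = runif(1, 0, 20), t_obs = 1,
                      n_timepoints = 10, spacing = 4)
    states <- mod$simulate(theta, eps, measurement_times(eps))
    expect_gte(min(states), -1e-8)
  }
})

test_that("state transitions over empty intervals are the identity", {
  fam <- six_models()
  th <- fam[[1]]$parameter_prior$components[[1]]$mean
  eps <- experiment(stimulus_strengths = c(1, 1))
  x <- runif(8, 0, 5)
  expect_identical(fam[[2]]$state_transition(x, th, eps, 3, 3), x)
  grn <- build_grn_demo_model()
  expect_identical(grn$state_transition(c(1, 2), c(1, 0.1, 1, 0.1), eps, 2, 2),
                   c(1, 2))
})

test_that("linear ODE transitions match closed forms and the semigroup law", {
  spec0 <- linear_ode_spec(matrix(0, 3, 3), rep(0, 3), rep(0, 3), a_ext = 0)
  x0 <- c(1, 2, 3, 4)
  expect_equal(linear_ode_transition(spec0, x0, 5), x0, tolerance = 1e-12)

  specI <- linear_ode_spec(-diag(3), rep(0, 3), rep(0, 3), a_ext = -1)
  expect_equal(linear_ode_transition(specI, rep(1, 4), 2),
               rep(exp(-2), 4), tolerance = 1e-12)

  # random stable system vs high-accuracy ODE integration
  set.seed(5)
  A <- matrix(rnorm(9, sd = 0.5), 3, 3); diag(A) <- -1.5
  spec <- linear_ode_spec(A, c(NA, 0, 0), c(0, 0, NA))
  th <- c(0.4, -0.3)
  J <- assemble_jacobian(spec, th)
  y_ode <- ode_rk45(function(t, y) as.numeric(J %*% y), rep(1, 4), 2.5,
                    rtol = 1e-11, atol = 1e-13)
  expect_equal(linear_ode_transition(spec, rep(1, 4), 2.5, th),
               y_ode[1, ], tolerance = 1e-8)

  # semigroup: phi(t1 + t2) = phi(t2) o phi(t1)
  x1 <- linear_ode_transition(spec, rep(1, 4), 1.2, th)
  x2 <- linear_ode_transition(spec, x1, 0.8, th)
  expect_equal(linear_ode_transition(spec, rep(1, 4), 2.0, th), x2,
               tolerance = 1e-8)

  # perturbations are additive on the named base entries
  specp <- linear_ode_spec(A, c(NA, 0, 0), c(0, 0, NA),
                           perturbations = list(list(i = 2, j = 1, delta = 0.3)))
  Jp <- assemble_jacobian(specp, th)
  expect_equal(Jp[2, 1], A[2, 1] + 0.3)
  expect_equal(Jp[-2, ] , J[-2, ])

  expect_error(assemble_jacobian(spec, c(Inf, 0)), "non-finite")
  expect_error(linear_ode_transition(spec, rep(1, 4), -1, th))
})

test_that("the compiled matrix exponential matches Matrix::expm", {
  skip_if_not_installed("Matrix")
  set.seed(8)
  for (d in c(2, 4, 6)) {
    M <- matrix(rnorm(d * d), d, d)
    expect_equal(utdesign:::.expm_cpp(M),
                 as.matrix(Matrix::expm(M)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("the mRNA/protein demo honours its experiment hooks", {
  grn <- build_grn_demo_model()
  th <- grn$parameter_prior$components[[1]]$mean

  # knockout: mRNA production identically zero regardless of repressor
  eps_ko <- experiment(t_obs = 30, extras = list(knockout = TRUE,
                                                 repressor = 0.1))
  states <- grn$simulate(th, eps_ko, c(10, 30))
  expect_equal(states, matrix(0, 2, 2), tolerance = 1e-10)

  # zero stimulus, zero initial state, zero production -> identically zero
  eps0 <- experiment(t_obs = 10)
  z <- grn$simulate(c(0, 0.1, 1, 0.1), eps0, c(5, 10))
  expect_equal(z, matrix(0, 2, 2), tolerance = 1e-10)

  # a stronger repressor lowers the mRNA steady state
  lo <- grn$simulate(th, experiment(t_obs = 1, extras = list(repressor = 0.5)),
                     150)
  hi <- grn$simulate(th, experiment(t_obs = 1, extras = list(repressor = 4)),
                     150)
  expect_gt(lo[1, 1], hi[1, 1])

  # stimulus pulse feeds the mRNA equation
  eps_s <- experiment(stimulus_strengths = c(2, 0), t_obs = 3)
  withs <- grn$simulate(th, eps_s, 3)
  without <- grn$simulate(th, eps0, 3)
  expect_gt(withs[1, 1], without[1, 1])
})

test_that("simulate_dataset is deterministic, noise-faithful and exact at zero noise", {
  fam <- six_models()
  truth <- fam[[4]]
  th <- truth$parameter_prior$components[[1]]$mean
  eps <- experiment(stimulus_strengths = c(5, 5), delay = 5, t_obs = 5,
                    n_timepoints = 4, spacing = 5)

  d1 <- simulate_dataset(truth, th, eps, seed = 3)
  d2 <- simulate_dataset(truth, th, eps, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(diff(d1$times) > 0))

  # zero measurement noise reproduces the noiseless trajectory exactly
  noiseless <- truth
  noiseless$measurement_noise <- 0
  d0 <- simulate_dataset(noiseless, th, eps, seed = 3)
  states <- truth$simulate(th, eps, measurement_times(eps))
  expect_equal(d0$values[, 1], states[, 8], tolerance = 1e-12)

  # empirical residual variances reflect the configured noise level
  for (v in c(0.01, 0.1)) {
    noisy <- build_crosstalk_family(list(list(c(1, 2, 2, 3))),
                                    measurement_noise = v)[[1]]
    res <- vapply(1:300, function(s)
      simulate_dataset(noisy, th, eps, seed = s)$values[1, 1] - states[1, 8],
      numeric(1))
    expect_equal(var(res), v, tolerance = 0.25)
  }

  # process noise perturbs the trajectory but stays seeded
  pn <- build_crosstalk_family(list(list(c(1, 2, 2, 3))),
                               process_noise_cov = diag(1e-4, 8))[[1]]
  p1 <- simulate_dataset(pn, th, eps, seed = 5)
  p2 <- simulate_dataset(pn, th, eps, seed = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1$values, d1$values))
})

test_that("dataset objects enforce their invariants", {
  expect_error(dataset(c(1, 1, 2), matrix(0, 3, 1)), "increasing")
  expect_error(dataset(1:3, matrix(c(1, NA, 3), 3, 1)), "missing")
  expect_error(dataset(1:3, matrix(0, 2, 1)), "nrow")
})
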