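## Desk-scale in-silico robustness studies.  These are first-class,
## seeded, reproducible study drivers; the full published scale
## (95 x 95 x 4 grids) is reached simply by raising the grid arguments.

#' Default experiment search bounds for the cascade fixtures
#'
#' Stimulus strengths in `[0, 5]`, delay in `[0, 50]`, first measurement
#' time in `[1, 50]`; a single measurement of the terminal species of
#' pathway 2 unless overridden.
#'
#' @param n_timepoints,spacing Fixed measurement schedule.
#' @return An [experiment_bounds()].
#' @export
cascade_bounds <- function(n_timepoints = 1L, spacing = 2) {
  experiment_bounds(
    lower = c(s1 = 0, s2 = 0, delay = 0, t_obs = 1),
    upper = c(s1 = 5, s2 = 5, delay = 50, t_obs = 50),
    fixed = list(n_timepoints = n_timepoints, spacing = spacing))
}

#' Default six-model crosstalk family
#'
#' The crosstalk-free model plus five single-link hypotheses from
#' pathway 1 to pathway 2 at different source/target positions.
#'
#' @param measurement_noise Scalar variance (default 0.01).
#' @return List of six `utd_ssm` objects.
#' @export
crosstalk_six_models <- function(measurement_noise = 0.01) {
  build_crosstalk_family(list(
    list(),
    list(c(1L, 1L, 2L, 2L)),
    list(c(1L, 2L, 2L, 2L)),
    list(c(1L, 2L, 2L, 3L)),
    list(c(1L, 3L, 2L, 3L)),
    list(c(1L, 3L, 2L, 4L))), measurement_noise = measurement_noise)
}

#' Score distribution of random experiments versus the designed one
#'
#' Samples `n` experiments uniformly from `bounds`, scores each by the
#' average pairwise Hellinger distance between the model prior
#' predictives, and runs the GA to obtain the designed experiment's score
#' on the same statistic.
#'
#' @param n Number of random experiments (>= 10).
#' @param bounds An [experiment_bounds()].
#' @param seed Integer seed.
#' @param models Model list (default [crosstalk_six_models()]).
#' @param config [ga_config()] for the designed comparison.
#' @param params [ut_params()].
#' @param breaks Histogram breaks (passed to [hist()][graphics::hist]
#'   logic via [cut()]); default 20 equal bins over `[0, 1]`.
#' @return List of class `utd_score_study`: `scores`, `designed_score`,
#'   `histogram` (data frame of bin mid, count), `design`
#'   (`utd_design_result`), `seed`.
#' @export
score_distribution_study <- function(n = 1000L, bounds = cascade_bounds(),
                                     seed = 1L, models = crosstalk_six_models(),
                                     config = ga_config(population = 40L,
                                                        generations = 25L),
                                     params = ut_params(), breaks = 20L) {
  stopifnot(n >= 10)
  avg_h <- function(H) mean(H[upper.tri(H)])
  scores <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      eps <- random_experiment(bounds)
      avg_h(pairwise_scores(models, eps, params = params, seed = seed))
    }, numeric(1))
  })
  des <- optimize_experiment(models, bounds, config = config, seed = seed,
                             params = params)
  designed_score <- avg_h(des$pairwise_hellinger)
  bins <- seq(0, 1, length.out = breaks + 1L)
  cnt <- table(cut(scores, bins, include.lowest = TRUE))
  histogram <- data.frame(bin_low = bins[-length(bins)], bin_high = bins[-1],
                          count = as.integer(cnt))
  structure(list(scores = scores, designed_score = designed_score,
                 histogram = histogram, design = des, seed = seed),
            class = "utd_score_study")
}

#' Selection frequencies over random experiments
#'
#' Fixes one of the 16 single-link crosstalk models as the true system,
#' performs `n_experiments` uniformly sampled experiments on it, and for
#' each dataset independently selects among the remaining 15 models,
#' counting how often each wins.
#'
#' @param n_experiments Number of random experiments (>= 10).
#' @param noise_variance Measurement-noise variance (paper settings: 0.01
#'   and 0.1).
#' @param seed Integer seed.
#' @param true_link `(source index, target index)` of the true model's
#'   pathway-1-to-2 connection (default `c(2, 3)`).
#' @param bounds An [experiment_bounds()].
#' @param params [ut_params()].
#' @return List of class `utd_frequency_study`: `counts` (named integer
#'   vector over the 15 candidates), `n_experiments`, `noise_variance`,
#'   `true_name`, `seed`.
#' @export
selection_frequency_study <- function(n_experiments = 1000L,
                                      noise_variance = 0.01, seed = 1L,
                                      true_link = c(2L, 3L),
                                      bounds = cascade_bounds(),
                                      params = ut_params()) {
  stopifnot(n_experiments >= 10)
  fam <- build_single_link_family(measurement_noise = noise_variance)
  nm <- vapply(fam, `[[`, character(1), "name")
  true_name <- paste0("links:1.", true_link[1], ">2.", true_link[2])
  ti <- match(true_name, nm)
  if (is.na(ti)) stop("true_link not found in the single-link family")
  truth <- fam[[ti]]
  candidates <- fam[-ti]
  cand_names <- nm[-ti]
  theta_true <- truth$parameter_prior$components[[1]]$mean
  wins <- integer(length(candidates))
  with_seed(seed, {
    for (i in seq_len(n_experiments)) {
      eps <- random_experiment(bounds)
      dseed <- sample.int(.Machine$integer.max - 1L, 1)
      D <- simulate_dataset(truth, theta_true, eps, seed = dseed)
      log_ev <- vapply(candidates, function(mod)
        log_marginal_likelihood(prior_predictive_deterministic(mod, eps,
                                                               params), D),
        numeric(1))
      w <- which.max(log_ev)
      wins[w] <- wins[w] + 1L
    }
  })
  names(wins) <- cand_names
  structure(list(counts = wins, n_experiments = n_experiments,
                 noise_variance = noise_variance, true_name = true_name,
                 seed = seed),
            class = "utd_frequency_study")
}

#' Posterior heat map over a grid of experiments
#'
#' Three single-link crosstalk models: two candidates and a designated
#' true system.  For every grid cell (stimulus delay x first measurement
#' time) data of each requested size are simulated from the true system
#' and the two-candidate posterior is computed independently per cell and
#' size.  Smaller data sizes are nested prefixes of the largest
#' measurement schedule, so each cell costs one predictive propagation per
#' model.
#'
#' @param delay_grid,t_obs_grid Grid axis values (defaults: 20 points over
#'   `[0, 50]` and `[1, 50]`).
#' @param data_sizes Increasing vector of measurement counts (default
#'   `c(1, 2, 4, 8)`).
#' @param seed Integer seed (per-cell data seeds are drawn from it).
#' @param candidate_links Two links for the candidate models (defaults
#'   `2 -> 2` and `3 -> 3`).
#' @param true_link Link of the true system (default `2 -> 3`).
#' @param noise_variance Measurement-noise variance.
#' @param spacing Measurement spacing (default 3).
#' @param stimulus_strengths Stimulus strengths used in every cell
#'   (default `c(5, 5)`).
#' @param observed_species Which species is measured (default 7, the
#'   crosstalk target; the terminal readout of pathway 2 is species 8).
#' @param params [ut_params()].
#' @param max_cells Guard on the grid size.
#' @return Object of class `utd_grid_result`: `table` (long data frame
#'   with `delay`, `t_obs`, `data_size`, `model`, `posterior`), axes and
#'   metadata.
#' @export
robustness_heatmap <- function(delay_grid = seq(0, 50, length.out = 20),
                               t_obs_grid = seq(1, 50, length.out = 20),
                               data_sizes = c(1L, 2L, 4L, 8L), seed = 1L,
                               candidate_links = list(c(2L, 2L), c(3L, 3L)),
                               true_link = c(2L, 3L), noise_variance = 0.01,
                               spacing = 3, stimulus_strengths = c(5, 5),
                               observed_species = 7L,
                               params = ut_params(), max_cells = 10000L) {
  n_cells <- length(delay_grid) * length(t_obs_grid)
  if (n_cells > max_cells) stop("grid larger than max_cells")
  data_sizes <- sort(as.integer(data_sizes))
  Tmax <- max(data_sizes)
  mk_link <- function(l) list(c(1L, l[1], 2L, l[2]))
  fam <- build_crosstalk_family(
    list(mk_link(candidate_links[[1]]), mk_link(candidate_links[[2]]),
         mk_link(true_link)),
    measurement_noise = noise_variance)
  cands <- fam[1:2]
  truth <- fam[[3]]
  theta_true <- truth$parameter_prior$components[[1]]$mean
  rows <- vector("list", n_cells * length(data_sizes) * 2L)
  ri <- 1L
  cell_seeds <- with_seed(seed, matrix(
    sample.int(.Machine$integer.max - 1L, n_cells),
    length(delay_grid), length(t_obs_grid)))
  for (a in seq_along(delay_grid)) {
    for (b in seq_along(t_obs_grid)) {
      eps <- experiment(stimulus_strengths = stimulus_strengths,
                        delay = delay_grid[a], t_obs = t_obs_grid[b],
                        n_timepoints = Tmax, spacing = spacing,
                        observation = list(species = observed_species,
                                           coef = 1))
      cellok <- TRUE
      preds <- tryCatch(lapply(cands, prior_predictive_deterministic,
                               eps = eps, params = params),
                        error = function(e) { cellok <<- FALSE; NULL })
      D <- if (cellok)
        tryCatch(simulate_dataset(truth, theta_true, eps,
                                  seed = cell_seeds[a, b]),
                 error = function(e) { cellok <<- FALSE; NULL }) else NULL
      for (sz in data_sizes) {
        post <- if (cellok) {
          idx <- seq_len(sz)
          Dsub <- dataset(D$times[idx], D$values[idx, , drop = FALSE])
          log_ev <- vapply(preds, function(p)
            log_marginal_likelihood(marginalize_predictive(p, idx), Dsub),
            numeric(1))
          posterior_probabilities(log_ev)
        } else c(NA_real_, NA_real_)
        for (mi in 1:2) {
          rows[[ri]] <- data.frame(delay = delay_grid[a],
                                   t_obs = t_obs_grid[b], data_size = sz,
                                   model = cands[[mi]]$name,
                                   posterior = post[mi])
          ri <- ri + 1L
        }
      }
    }
  }
  structure(list(table = do.call(rbind, rows), delay_grid = delay_grid,
                 t_obs_grid = t_obs_grid, data_sizes = data_sizes,
                 model_names = vapply(cands, `[[`, character(1), "name"),
                 true_name = truth$name, noise_variance = noise_variance,
                 seed = seed),
            class = "utd_grid_result")
}

#' Model-inaccuracy perturbation scan for linear-ODE extensions
#'
#' For every pair of additive perturbations `(delta1, delta2)` applied to
#' two designated base-Jacobian entries, both extension hypotheses (true
#' and false) are built on the same perturbed base, first-variable data
#' are simulated from the unperturbed true system, and the outcome is
#' classified as `true-extension` or `false-extension` (Bayes factor above
#' the Jeffreys "substantial" cut), `inconclusive`, or `numerical-floor`
#' (both log evidences below `log_evidence_floor`).
#'
#' @param delta1_grid,delta2_grid Perturbation axes (defaults 41 points
#'   over `[-1, 1]`).
#' @param seed Integer seed (data noise and prior fit).
#' @param base_A Base Jacobian (default: species 1 and 2 form a damped
#'   oscillator, species 3 is driven by 2 and feeds back into 1; the
#'   oscillation gives species 1 and 2 distinct temporal shapes so the
#'   extension's driver is identifiable).
#' @param perturb_entries List of two `(i, j)` index pairs receiving
#'   `delta1` and `delta2` (defaults `(2, 1)` and `(3, 2)`).
#' @param true_b,false_b,ext_c Extension row/column patterns (`NA` = free
#'   strength); defaults: the true extension is driven by species 1, the
#'   false one by species 2, both feeding back into species 1 (the
#'   observed variable).
#' @param theta_true True interaction strengths of the generating system.
#' @param times Measurement times (default `1:8`).
#' @param noise_variance Measurement-noise variance (default 0.001).
#' @param prior_K Mixture components for the interaction-strength prior.
#' @param bf_threshold Bayes-factor cut (default `10^0.5`).
#' @param log_evidence_floor Numerical-trust floor (default `log(1e-40)`).
#' @param params [ut_params()].
#' @return Object of class `utd_perturbation_map`: `table` (long data
#'   frame with `delta1`, `delta2`, `log_ev_true`, `log_ev_false`,
#'   `category`), grids, thresholds, `seed`.
#' @export
perturbation_study <- function(delta1_grid = seq(-1, 1, length.out = 41),
                               delta2_grid = seq(-1, 1, length.out = 41),
                               seed = 1L,
                               base_A = rbind(c(-0.5, -1, 0.3),
                                              c(1, -0.5, 0),
                                              c(0, 0.5, -1)),
                               perturb_entries = list(c(2L, 1L), c(3L, 2L)),
                               true_b = c(NA, 0, 0), false_b = c(0, NA, 0),
                               ext_c = c(NA, 0, 0),
                               theta_true = c(0.9, -0.9), times = 1:8,
                               noise_variance = 0.001, prior_K = 5L,
                               bf_threshold = 10^0.5,
                               log_evidence_floor = log(1e-40),
                               params = ut_params()) {
  prior <- fit_mixture_to_box(rep(-1, 2), rep(1, 2), K = prior_K, seed = seed)
  eps <- experiment(t_obs = times[1], n_timepoints = length(times),
                    spacing = if (length(times) > 1) diff(times)[1] else 1)
  ## data from the unperturbed truth (true extension, true strengths)
  truth_spec <- linear_ode_spec(base_A, true_b, ext_c, prior = prior)
  truth <- build_linear_extension_model(truth_spec, name = "truth",
                                        measurement_noise = noise_variance)
  D <- simulate_dataset(truth, theta_true, eps, seed = seed)
  classify <- function(lt, lf) {
    if (lt < log_evidence_floor && lf < log_evidence_floor)
      return("numerical-floor")
    bf <- exp(lt - lf)
    if (bf >= bf_threshold) "true-extension"
    else if (bf <= 1 / bf_threshold) "false-extension"
    else "inconclusive"
  }
  rows <- vector("list", length(delta1_grid) * length(delta2_grid))
  ri <- 1L
  for (a in seq_along(delta1_grid)) {
    for (b in seq_along(delta2_grid)) {
      perts <- list(
        list(i = perturb_entries[[1]][1], j = perturb_entries[[1]][2],
             delta = delta1_grid[a]),
        list(i = perturb_entries[[2]][1], j = perturb_entries[[2]][2],
             delta = delta2_grid[b]))
      mt <- build_linear_extension_model(
        linear_ode_spec(base_A, true_b, ext_c, perturbations = perts,
                        prior = prior),
        name = "true-extension", measurement_noise = noise_variance)
      mf <- build_linear_extension_model(
        linear_ode_spec(base_A, false_b, ext_c, perturbations = perts,
                        prior = prior),
        name = "false-extension", measurement_noise = noise_variance)
      lt <- log_marginal_likelihood(
        prior_predictive_deterministic(mt, eps, params), D)
      lf <- log_marginal_likelihood(
        prior_predictive_deterministic(mf, eps, params), D)
      rows[[ri]] <- data.frame(delta1 = delta1_grid[a],
                               delta2 = delta2_grid[b], log_ev_true = lt,
                               log_ev_false = lf,
                               category = classify(lt, lf))
      ri <- ri + 1L
    }
  }
  structure(list(table = do.call(rbind, rows), delta1_grid = delta1_grid,
                 delta2_grid = delta2_grid,
                 thresholds = list(bf = bf_threshold,
                                   floor = log_evidence_floor),
                 seed = seed),
            class = "utd_perturbation_map")
}

#' Re-classify a perturbation map under a different evidence floor
#'
#' @param pmap A [perturbation_study()] result.
#' @param log_evidence_floor New floor.
#' @return A `utd_perturbation_map` with updated categories.
#' @export
reclassify_perturbation_map <- function(pmap, log_evidence_floor) {
  tb <- pmap$table
  bf_threshold <- pmap$thresholds$bf
  tb$category <- mapply(function(lt, lf) {
    if (lt < log_evidence_floor && lf < log_evidence_floor)
      return("numerical-floor")
    bf <- exp(lt - lf)
    if (bf >= bf_threshold) "true-extension"
    else if (bf <= 1 / bf_threshold) "false-extension"
    else "inconclusive"
  }, tb$log_ev_true, tb$log_ev_false)
  pmap$table <- tb
  pmap$thresholds$floor <- log_evidence_floor
  pmap
}
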