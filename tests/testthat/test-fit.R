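sim_obs <- function(n_species, n_focal, seed, alpha = NULL, density = 4,
                    dispersion = 2, log_lambda = log(50), n_plots = 1) {
  d <- small_design(n_species = n_species, n_plots = n_plots)
  tr <- make_truth(d, occupancy = 1, alpha = alpha, density = density,
                   dispersion = dispersion, log_lambda = log_lambda,
                   seed = seed)
  list(design = d, truth = tr,
       obs = generate_observations(tr, d, n_focal, seed = seed + 100))
}

test_that("intercept-only data recovers the sample mean as lambda-hat", {
  s <- sim_obs(2, n_focal = 200, seed = 21, alpha = 0, density = 0)
  fit <- fit_homogeneous(s$obs, s$truth$g, s$truth$s, year = 2015)
  for (f in s$design$species_names) {
    y <- s$obs$seeds[s$obs$focal == f]
    expect_equal(unname(fit$log_lambda[f]), log(mean(y)), tolerance = 1e-6)
    # neighbor columns all zero: coefficients fixed at zero and flagged
    expect_true(all(fit$alpha[f, ] == 0))
    expect_true(all(fit$fit_flags$alpha[f, ] == "fixed_zero_unobserved"))
  }
})

test_that("fitted parameters recover an interaction-free truth within 3 SE", {
  s <- sim_obs(5, n_focal = 300, seed = 7)
  s$truth$alpha[] <- 0
  s$truth$alpha_plot[] <- 0
  obs <- generate_observations(s$truth, s$design, 300, seed = 107)
  fit <- fit_homogeneous(obs, s$truth$g, s$truth$s, year = 2015)
  for (f in s$design$species_names) {
    expect_lt(abs(fit$log_lambda[f] - s$truth$log_lambda[f, 1]),
              3 * fit$standard_errors$log_lambda[f])
  }

  # MLE property: likelihood at the optimum beats the truth parameters
  truth_params <- community_params(
    year = 2015, plot = "ALL", species = s$design$species_names,
    log_lambda = s$truth$log_lambda[, 1], alpha = s$truth$alpha,
    g = s$truth$g, s = s$truth$s, dispersion = s$truth$dispersion
  )
  expect_gte(neg_binomial_ricker_loglik(fit, obs),
             neg_binomial_ricker_loglik(truth_params, obs))
})

test_that("a known pairwise interaction strength is recovered within 3 SE", {
  d <- small_design(n_species = 2)
  alpha <- matrix(c(0.05, 0.2, 0.0, 0.06), 2, 2, byrow = TRUE)
  tr <- make_truth(d, occupancy = 1, alpha = alpha, density = 5,
                   dispersion = 2.5, log_lambda = log(80), seed = 31)
  obs <- generate_observations(tr, d, n_focal_per_species_plot = 500,
                               seed = 131)
  fit <- fit_homogeneous(obs, tr$g, tr$s, year = 2015)
  sp <- d$species_names
  est <- fit$alpha[sp[1], sp[2]]
  se <- fit$standard_errors$alpha[sp[1], sp[2]]
  expect_lt(abs(est - 0.2), 3 * se)
})

test_that("estimates are invariant to row order", {
  s <- sim_obs(3, n_focal = 80, seed = 41)
  fit1 <- fit_homogeneous(s$obs, s$truth$g, s$truth$s, year = 2015)
  obs_shuffled <- s$obs[withr::with_seed(1, sample(nrow(s$obs))), ]
  fit2 <- fit_homogeneous(obs_shuffled, s$truth$g, s$truth$s, year = 2015)
  expect_equal(fit1$log_lambda, fit2$log_lambda, tolerance = 1e-8)
  expect_equal(fit1$alpha, fit2$alpha, tolerance = 1e-8)
})

test_that("Wald interval coverage for log lambda is calibrated", {
  hits <- 0
  total <- 0
  for (rep in 1:20) {
    s <- sim_obs(1, n_focal = 150, seed = 500 + rep, density = 3)
    fit <- fit_homogeneous(s$obs, s$truth$g, s$truth$s, year = 2015)
    f <- s$design$species_names
    ci <- fit$log_lambda[f] + c(-1.96, 1.96) *
      fit$standard_errors$log_lambda[f]
    truth_ll <- s$truth$log_lambda[f, 1]
    hits <- hits + (truth_ll >= ci[1] && truth_ll <= ci[2])
    total <- total + 1
  }
  expect_gte(hits / total, 0.85)
})

test_that("tight shrinkage collapses the heterogeneous fit onto the pooled fit", {
  s <- sim_obs(3, n_focal = 40, seed = 51, n_plots = 3)
  pooled <- fit_homogeneous(s$obs, s$truth$g, s$truth$s, year = 2015)
  het <- fit_heterogeneous(s$obs, s$truth$g, s$truth$s, year = 2015,
                           shrinkage_sd = 1e-5, pooled = pooled)
  for (p in names(het)) {
    expect_equal(het[[p]]$log_lambda, pooled$log_lambda[het[[p]]$species],
                 tolerance = 1e-3)
    expect_equal(het[[p]]$alpha,
                 pooled$alpha[het[[p]]$species, het[[p]]$species],
                 tolerance = 1e-3)
  }
  expect_error(fit_heterogeneous(s$obs, s$truth$g, s$truth$s, year = 2015,
                                 shrinkage_sd = 0), "shrinkage_sd")
})

test_that("with a single plot the heterogeneous fit equals the pooled fit", {
  s <- sim_obs(3, n_focal = 60, seed = 61, n_plots = 1)
  pooled <- fit_homogeneous(s$obs, s$truth$g, s$truth$s, year = 2015)
  het <- fit_heterogeneous(s$obs, s$truth$g, s$truth$s, year = 2015,
                           shrinkage_sd = 0.5, pooled = pooled)
  expect_length(het, 1)
  expect_equal(het[[1]]$log_lambda, pooled$log_lambda, tolerance = 1e-5)
  expect_equal(het[[1]]$alpha, pooled$alpha, tolerance = 1e-5)
})

test_that("parameter replicate draws honor count, determinism and zero-SE", {
  s <- sim_obs(2, n_focal = 60, seed = 71)
  fit <- fit_homogeneous(s$obs, s$truth$g, s$truth$s, year = 2015)
  draws <- draw_parameter_replicates(fit, n_draws = 100, seed = 5)
  expect_length(draws, 100)
  draws2 <- draw_parameter_replicates(fit, n_draws = 100, seed = 5)
  expect_identical(draws, draws2)
  expect_false(identical(draws[[1]]$log_lambda, draws[[2]]$log_lambda))

  fit0 <- fit
  fit0$standard_errors$log_lambda[] <- 0
  fit0$standard_errors$alpha[] <- 0
  fit0$standard_errors$dispersion[] <- 0
  d0 <- draw_parameter_replicates(fit0, n_draws = 5, seed = 5)
  for (dd in d0) {
    expect_identical(dd$log_lambda, fit0$log_lambda)
    expect_identical(dd$alpha, fit0$alpha)
  }

  fit_na <- fit
  fit_na$standard_errors <- NULL
  expect_error(draw_parameter_replicates(fit_na, 5, seed = 1),
               "standard errors")
})
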