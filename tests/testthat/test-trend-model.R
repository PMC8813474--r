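test_that("logit and inverse logit are mutual inverses with the expected values", {
  expect_equal(logit(0.5), 0)
  expect_equal(inv_logit(0), 0.5)
  expect_equal(logit(0.8), log(4))
  p <- runif(50, 0.01, 0.99)
  expect_equal(inv_logit(logit(p)), p)
  expect_error(logit(0), "clamp")
  expect_error(logit(1), "clamp")
  expect_equal(clamp_coverage(c(0, 1), 100), c(0.005, 0.995))
})

test_that("mcmc_config validates and reads from YAML", {
  cfg <- mcmc_config()
  expect_equal(cfg$n_iter, 10000L)
  expect_equal(cfg$n_chains, 3L)
  expect_equal(cfg$thin, 10L)
  expect_equal(cfg$burn_in, 500L)
  expect_error(mcmc_config(n_iter = 100, burn_in = 200))
  expect_error(mcmc_config(thin = 0))

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_iter: 2000", "burn_in: 100", "thin: 2", "seed: 9",
               "prior_family_sd: uniform", "use_covariates: no"), path)
  cfg2 <- read_mcmc_config(path)
  expect_equal(cfg2$n_iter, 2000L)
  expect_equal(cfg2$prior_family_sd, "uniform")
  expect_false(cfg2$use_covariates)
  writeLines("bogus_key: 1", path)
  expect_error(read_mcmc_config(path), "unknown config keys")
})

test_that("log posterior reduces to the prior with no data and matches a direct formula", {
  cfg <- mcmc_config(use_covariates = FALSE)
  params <- list(alpha = c(S01 = 0.3), beta = c(S01 = 0.8),
                 gamma_sdi = 0.1, gamma_hrh = -0.2,
                 mu_alpha = 0.2, mu_beta = 0.7,
                 sigma_alpha = 1.1, sigma_beta = 0.4)
  empty <- make_survey_tbl()[0, ]
  lp <- trend_log_posterior(params, empty, config = cfg)
  direct <- sum(dnorm(c(0.2, 0.7, 0.1, -0.2), 0, 100, log = TRUE)) -
    log1p((1.1 / 2.5)^2) - log1p((0.4 / 2.5)^2) +
    dnorm(0.3, 0.2, 1.1, log = TRUE) + dnorm(0.8, 0.7, 0.4, log = TRUE)
  expect_equal(lp, direct)
  expect_equal(trend_log_posterior(modifyList(params, list(sigma_alpha = -1)),
                                   empty, config = cfg), -Inf)
  expect_error(trend_log_posterior(modifyList(params, list(mu_alpha = NaN)),
                                   empty, config = cfg), "non-finite")
})

test_that("a flat-prior single-observation posterior peaks at the empirical logit", {
  cfg <- mcmc_config(use_covariates = FALSE, hierarchical = FALSE,
                     fit_slope = FALSE, prior_scale_fixed = 1e4)
  obs <- make_survey_tbl(years = 2000L, coverage = 0.63, n_effective = 200)
  grid <- seq(logit(0.63) - 0.5, logit(0.63) + 0.5, by = 1e-4)
  lp <- vapply(grid, function(a) {
    trend_log_posterior(list(alpha = c(S01 = a), beta = c(S01 = 0),
                             gamma_sdi = 0, gamma_hrh = 0, mu_alpha = 0,
                             mu_beta = 0, sigma_alpha = 1, sigma_beta = 1),
                        obs, config = cfg)
  }, numeric(1))
  expect_equal(grid[which.max(lp)], logit(0.63), tolerance = 1e-3)
})

test_that("the binomial likelihood is symmetric under outcome reflection", {
  cfg <- mcmc_config(use_covariates = FALSE, hierarchical = FALSE)
  obs <- make_survey_tbl(years = c(2004L, 2012L), coverage = c(0.3, 0.55),
                         n_effective = 500)
  refl <- obs
  refl$coverage <- 1 - refl$coverage
  base <- list(alpha = c(S01 = 0.4), beta = c(S01 = 0.9), gamma_sdi = 0,
               gamma_hrh = 0, mu_alpha = 0, mu_beta = 0,
               sigma_alpha = 1, sigma_beta = 1)
  neg <- modifyList(base, list(alpha = c(S01 = -0.4), beta = c(S01 = -0.9)))
  # priors are symmetric around zero, so the full posterior is invariant
  expect_equal(trend_log_posterior(base, obs, config = cfg),
               trend_log_posterior(neg, refl, config = cfg))
})

test_that("fits are seed-deterministic with the contracted draw count", {
  pts <- make_survey_tbl()
  cfg <- mcmc_config(n_iter = 700, burn_in = 150, thin = 7, seed = 42,
                     use_covariates = FALSE, hierarchical = FALSE)
  f1 <- fit_trend(pts, config = cfg)
  f2 <- fit_trend(pts, config = cfg)
  expect_identical(f1$chains, f2$chains)
  expect_equal(nrow(f1$chains[[1]]), (700 - 150) %/% 7)
  expect_length(f1$chains, 3)
  f3 <- fit_trend(pts, config = mcmc_config(n_iter = 700, burn_in = 150,
                                            thin = 7, seed = 43,
                                            use_covariates = FALSE,
                                            hierarchical = FALSE))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("exchangeable countries get equal posteriors within Monte Carlo error", {
  pts <- dplyr::bind_rows(make_survey_tbl("S01"), make_survey_tbl("S02"))
  fit <- fit_trend(pts, config = mcmc_config(n_iter = 4000, burn_in = 500,
                                             thin = 5, seed = 3,
                                             use_covariates = FALSE))
  draws <- do.call(rbind, fit$chains)
  for (p in c("alpha", "beta")) {
    d1 <- draws[, paste0(p, "[S01]")]
    d2 <- draws[, paste0(p, "[S02]")]
    mcse <- sd(d1 - d2) / sqrt(length(d1) / 5) # conservative ESS guess
    expect_lt(abs(mean(d1) - mean(d2)), 3 * mcse + 1e-8)
  }
})

test_that("a country with no data shrinks to the hyper-mean", {
  spec <- generator_spec(n_countries = 6, surveys_per_country = 4, seed = 17)
  truth <- generate_trajectories(spec)
  sv <- generate_surveys(truth, spec)
  fit <- fit_trend(sv, truth$covariates,
                   mcmc_config(n_iter = 3000, burn_in = 500, thin = 5, seed = 2),
                   countries = c(sort(unique(sv$country_iso)), "S99"))
  draws <- do.call(rbind, fit$chains)
  diff <- draws[, "alpha[S99]"] - draws[, "mu_alpha"]
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(length(diff) / 5))
})

test_that("single-country flat-prior posterior matches the conjugate Beta law", {
  s <- 60
  f <- 40
  pts <- make_survey_tbl(years = 2010L, coverage = s / (s + f),
                         n_effective = s + f)
  fit <- fit_trend(pts, config = mcmc_config(
    n_iter = 4000, burn_in = 500, thin = 5, seed = 5,
    use_covariates = FALSE, hierarchical = FALSE, fit_slope = FALSE,
    intercept_prior = "logistic"
  ))
  p <- inv_logit(do.call(rbind, fit$chains)[, "alpha[S01]"])
  ks <- suppressWarnings(stats::ks.test(p, stats::pbeta, s + 1, f + 1))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("zero-slope draws project to a flat trajectory and means preserve monotonicity", {
  flat <- make_fake_trend_fit(alpha_draws = rnorm(200, 0.4, 0.3),
                              beta_draws = rep(0, 200))
  traj <- project_coverage(flat, years = 2000:2030)
  expect_equal(dplyr::n_distinct(round(traj$mean, 10)), 1)
  expect_true(all(traj$cri_low <= traj$mean & traj$mean <= traj$cri_high))

  rising <- make_fake_trend_fit(alpha_draws = rnorm(200, -1, 0.5),
                                beta_draws = runif(200, 0.2, 1.5))
  traj2 <- project_coverage(rising, years = 2000:2030)
  expect_true(all(diff(traj2$mean) > 0))
  expect_true(all(traj2$mean > 0 & traj2$mean < 100))
})

test_that("projection demands covariates unless extrapolation is enabled", {
  spec <- generator_spec(n_countries = 3, surveys_per_country = 3, seed = 9)
  truth <- generate_trajectories(spec)
  sv <- generate_surveys(truth, spec)
  short_cov <- dplyr::filter(truth$covariates, year <= 2019)
  fit <- fit_trend(sv, short_cov,
                   mcmc_config(n_iter = 600, burn_in = 100, thin = 2, seed = 1))
  expect_error(project_coverage(fit, years = 2000:2030), "missing projection-year")
  traj <- project_coverage(fit, years = 2000:2030, extrapolate = TRUE)
  expect_equal(nrow(traj), 3 * 31)
})

test_that("covariate extrapolation fills to the horizon and respects bounds", {
  cov <- make_covariates_tbl("S01", 2000:2019)
  ext <- extrapolate_covariates(cov, 2030)
  expect_equal(nrow(ext), 31)
  expect_equal(nrow(covariate_gaps(ext, 2000:2030)), 0)
  expect_true(all(ext$sdi >= 0 & ext$sdi <= 1))
  expect_true(all(ext$hrh >= 0))
})

test_that("per-stratum fitting returns one independent fit per stratum", {
  spec <- generator_spec(n_countries = 3, surveys_per_country = 3, seed = 13)
  truth <- generate_trajectories(spec)
  sv <- generate_surveys(truth, spec, strata = c("urban", "rural"))
  fits <- fit_trend_strata(sv, truth$covariates,
                           mcmc_config(n_iter = 600, burn_in = 100, thin = 2,
                                       seed = 1))
  expect_named(fits, c("rural", "urban"))
  expect_s3_class(fits$urban, "trend_fit")
  expect_equal(fits$urban$stratum, "urban")
  expect_error(fit_trend(sv, truth$covariates), "one outcome and one stratum")
})

test_that("the region hierarchy adds region-level means when enabled", {
  spec <- generator_spec(n_countries = 6, n_regions = 2,
                         surveys_per_country = 3, seed = 21)
  truth <- generate_trajectories(spec)
  sv <- generate_surveys(truth, spec)
  fit <- fit_trend(sv, truth$covariates,
                   mcmc_config(n_iter = 800, burn_in = 200, thin = 2, seed = 2,
                               region_hierarchy = TRUE))
  draws <- do.call(rbind, fit$chains)
  reg_cols <- grep("^mu_alpha_region", colnames(draws), value = TRUE)
  expect_length(reg_cols, 2)
  expect_gt(min(apply(draws[, reg_cols], 2, sd)), 0)
})

test_that("tidy and glance summarise fits in the broom shape", {
  pts <- make_survey_tbl()
  fit <- fit_trend(pts, config = mcmc_config(n_iter = 600, burn_in = 100,
                                             thin = 2, seed = 1,
                                             use_covariates = FALSE,
                                             hierarchical = FALSE))
  td <- tidy(fit)
  expect_true(all(c("parameter", "mean", "median", "cri_low", "cri_high",
                    "psrf_point") %in% names(td)))
  expect_true(all(td$cri_low <= td$median & td$median <= td$cri_high))
  g <- glance(fit)
  expect_equal(g$n_obs, 4L)
  expect_equal(g$n_draws, 250L)
  draws_tbl <- posterior_draws(fit, "alpha[S01]")
  expect_equal(nrow(draws_tbl), 3 * 250)
})

test_that("draws persist to a long-format CSV", {
  fit <- make_fake_trend_fit(rnorm(20), rnorm(20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_draws(fit, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 20 * 10)
  expect_named(back, c("chain", "iteration", "parameter", "value"))
})
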