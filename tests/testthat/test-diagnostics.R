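test_that("PSRF matches the hand-computed two-identical-chain example", {
  rep <- gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  # W = 5/3, B/n = 0, V = (3/4) W, so sqrt(V/W) = sqrt(0.75)
  expect_equal(rep$psrf_point, sqrt(0.75))
  expect_equal(rep$psrf_upper, sqrt(0.75))
  expect_false(rep$flag)
})

test_that("degenerate chains are signalled rather than silently infinite", {
  expect_error(gelman_rubin(list(rep(1, 4), rep(2, 4))), "degenerate")
  expect_error(gelman_rubin(list(1:4)), "at least two")
  expect_error(gelman_rubin(list(1:3, 1:3)), "length at least 4")
  expect_error(gelman_rubin(list(1:4, 1:5)), "equal length")
})

test_that("long stationary chains give PSRF near one and get flagged correctly", {
  set.seed(99)
  chains <- list(rnorm(5000), rnorm(5000))
  rep <- gelman_rubin(chains)
  expect_lte(rep$psrf_point, 1.02)
  expect_gte(rep$psrf_upper, rep$psrf_point)
  expect_false(rep$flag)
  # clearly separated chains must be flagged
  bad <- gelman_rubin(list(rnorm(100), rnorm(100) + 5))
  expect_true(bad$flag)
  expect_gt(bad$psrf_point, 1.1)
})

test_that("PSRF is invariant to affine maps and chain order", {
  set.seed(7)
  chains <- list(rnorm(60, 1), rnorm(60, 1.2), rnorm(60, 0.8))
  base <- gelman_rubin(chains)
  shifted <- gelman_rubin(lapply(chains, function(x) 3.7 * x - 11))
  expect_equal(shifted$psrf_point, base$psrf_point)
  expect_equal(shifted$psrf_upper, base$psrf_upper)
  permuted <- gelman_rubin(chains[c(2, 3, 1)])
  expect_equal(permuted$psrf_point, base$psrf_point)
})

test_that("PSRF agrees with an ANOVA-route reference on random chain sets", {
  set.seed(1234)
  for (i in 1:50) {
    m <- sample(2:5, 1)
    n <- sample(c(10, 25, 80), 1)
    chains <- lapply(seq_len(m),
                     function(j) rnorm(n, mean = runif(1, -1, 1),
                                       sd = runif(1, 0.5, 2)))
    expect_equal(gelman_rubin(chains)$psrf_point, psrf_anova_oracle(chains),
                 tolerance = 1e-8)
  }
})

test_that("the split-chain variant detects within-chain drift", {
  trended <- list(seq(0, 5, length.out = 400) + rnorm(400, 0, 0.1),
                  seq(0, 5, length.out = 400) + rnorm(400, 0, 0.1))
  expect_false(gelman_rubin(trended)$flag)       # classic variant is blind
  expect_true(gelman_rubin(trended, split = TRUE)$flag)
})

test_that("trace summaries track running means and the pooled mean", {
  const <- trace_summary(rep(3.5, 10))
  expect_true(all(const$running_mean == 3.5))
  alt <- trace_summary(list(rep(c(0, 1), 50), rep(c(1, 0), 50)))
  expect_equal(attr(alt, "pooled_mean"), 0.5)
  expect_error(trace_summary(list()), "non-empty")
})

test_that("fit-level diagnostics cover every monitored parameter", {
  pts <- dplyr::bind_rows(make_survey_tbl("S01"),
                          make_survey_tbl("S02", coverage = c(0.3, 0.4, 0.5, 0.6)))
  fit <- fit_trend(pts, config = mcmc_config(n_iter = 600, burn_in = 100,
                                             thin = 2, seed = 1,
                                             use_covariates = FALSE))
  expect_setequal(fit$diagnostics$parameter, fit$monitored)
  expect_true(all(fit$diagnostics$psrf_upper >= fit$diagnostics$psrf_point))
  acc <- acceptance_rates(fit)
  expect_true(all(acc$acceptance >= 0 & acc$acceptance <= 1, na.rm = TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_diagnostics(fit$diagnostics, path)
  expect_true(file.exists(path))
})
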