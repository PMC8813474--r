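make_fake_determinant_fit <- function(coef_value = 0, n_draws = 50) {
  lv <- individual_levels()
  cols <- unlist(purrr::imap(lv, function(levels, v) paste0(v, ":", levels[-1])))
  par_names <- c("(Intercept)", cols, "u[S01]", "u[S02]", "sigma2_u0")
  m <- matrix(coef_value, n_draws, length(par_names),
              dimnames = list(NULL, par_names))
  m[, "sigma2_u0"] <- 1
  structure(list(
    chains = list(m), parameters = par_names,
    monitored = c("(Intercept)", cols, "sigma2_u0"),
    columns = unname(cols), reference = vapply(lv, `[`, character(1), 1),
    countries = c("S01", "S02"), outcome = "INSD",
    config = suppressWarnings(mcmc_config(n_chains = 1)),
    random_intercept = TRUE,
    n_obs = 0L, acceptance = tibble::tibble()
  ), class = "determinant_fit")
}

test_that("the design encoding has 21 non-reference columns with correct dummies", {
  spec <- generator_spec(n_countries = 2, seed = 5)
  rec <- generate_individuals(spec, n_per_country = 40)
  d <- encode_design(rec)
  expect_equal(ncol(d$x), 21)
  expect_equal(nrow(d$x), nrow(rec))
  expect_equal(length(d$columns), 21)

  ref_row <- rec[1, ]
  lv <- individual_levels()
  for (v in names(lv)) ref_row[[v]] <- lv[[v]][1]
  d_ref <- encode_design(ref_row)
  expect_true(all(d_ref$x == 0))

  hi <- ref_row
  hi$education <- "higher"
  d_hi <- encode_design(hi)
  expect_equal(sum(d_hi$x), 1)
  expect_equal(unname(d_hi$x[1, "education:higher"]), 1)
})

test_that("odds-ratio tables expose the published row structure", {
  fit0 <- make_fake_determinant_fit(0)
  tab <- or_table(fit0)
  expect_true(all(tab$or[tab$characteristic != "random_intercept"] == 1))
  ref_levels <- dplyr::filter(tab, reference)$level
  expect_setequal(ref_levels, c("<30", "male", "none", "1", "0", "Q1", "urban"))
  # one row per level of each characteristic plus the variance line
  lv <- individual_levels()
  expect_equal(nrow(tab), sum(lengths(lv)) + 1)
  expect_equal(tab$level[nrow(tab)], "sigma2_u0")
  # reference rows print OR 1.00 with no interval
  refs <- dplyr::filter(tab, reference)
  expect_equal(nrow(refs), 8)
  expect_true(all(refs$or == 1 & is.na(refs$cri_low)))

  fit2 <- make_fake_determinant_fit(log(2))
  tab2 <- or_table(fit2)
  rural <- dplyr::filter(tab2, level == "rural")
  expect_equal(rural$or, 2)
  expect_equal(rural$cri_low, 2)
  expect_equal(rural$cri_high, 2)
})

test_that("complete separation is reported before sampling", {
  spec <- generator_spec(n_countries = 2, seed = 8)
  rec <- generate_individuals(spec, n_per_country = 100)
  rec$outcome_insd[rec$residence == "rural"] <- 1L
  expect_error(
    fit_determinants(rec, "INSD",
                     mcmc_config(n_iter = 200, burn_in = 50, thin = 1,
                                 seed = 1, prior_scale_fixed = 10)),
    "complete separation.*residence:rural")
})

test_that("swapping the outcome negates the coefficient posteriors", {
  spec <- generator_spec(n_countries = 2, seed = 12)
  rec <- generate_individuals(spec, n_per_country = 500)
  cfg <- mcmc_config(n_iter = 1500, burn_in = 300, thin = 3, seed = 4,
                     prior_scale_fixed = 10)
  fit <- fit_determinants(rec, "INSD", cfg)
  flipped <- rec
  flipped$outcome_insd <- 1L - flipped$outcome_insd
  fit_f <- fit_determinants(flipped, "INSD", cfg)
  a <- colMeans(do.call(rbind, fit$chains))
  b <- colMeans(do.call(rbind, fit_f$chains))
  for (p in c("(Intercept)", "residence:rural", "wealth_quintile:Q5")) {
    expect_equal(a[[p]], -b[[p]], tolerance = 0.15)
  }
})

test_that("determinant fits are seed-deterministic and carry diagnostics", {
  spec <- generator_spec(n_countries = 2, seed = 19)
  rec <- generate_individuals(spec, n_per_country = 300)
  cfg <- mcmc_config(n_iter = 600, burn_in = 150, thin = 3, seed = 6,
                     prior_scale_fixed = 10)
  f1 <- fit_determinants(rec, "INSD", cfg)
  f2 <- fit_determinants(rec, "INSD", cfg)
  expect_identical(f1$chains, f2$chains)
  expect_equal(nrow(f1$chains[[1]]), (600 - 150) %/% 3)
  expect_true(all(c("(Intercept)", "sigma2_u0") %in% f1$diagnostics$parameter))
  g <- glance(f1)
  expect_equal(g$n_obs, 600L)
  expect_equal(g$outcome, "INSD")
  expect_error(fit_determinants(rec[rec$country_iso == "S01", ], "INSD", cfg),
               "at least 2 countries")
})

test_that("duplicating every record sharpens intervals without moving the centre", {
  spec <- generator_spec(n_countries = 2, seed = 23)
  rec <- generate_individuals(spec, n_per_country = 1200)
  cfg <- mcmc_config(n_iter = 1500, burn_in = 300, thin = 3, seed = 2,
                     prior_scale_fixed = 10)
  fit1 <- fit_determinants(rec, "INSD", cfg)
  fit2 <- fit_determinants(dplyr::bind_rows(rec, rec), "INSD", cfg)
  t1 <- dplyr::filter(or_table(fit1), level == "rural")
  t2 <- dplyr::filter(or_table(fit2), level == "rural")
  expect_lt(t2$cri_high - t2$cri_low, t1$cri_high - t1$cri_low)
  expect_equal(log(t2$or), log(t1$or), tolerance = 0.15)
})
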