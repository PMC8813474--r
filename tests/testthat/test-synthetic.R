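test_that("generation is deterministic in the spec seed", {
  spec <- generator_spec(n_countries = 4, seed = 77)
  t1 <- generate_trajectories(spec)
  t2 <- generate_trajectories(spec)
  expect_identical(t1$truth, t2$truth)
  expect_identical(generate_surveys(t1, spec), generate_surveys(t2, spec))
  expect_identical(generate_individuals(spec, 50), generate_individuals(spec, 50))
  t3 <- generate_trajectories(generator_spec(n_countries = 4, seed = 78))
  expect_false(identical(t1$truth, t3$truth))
})

test_that("a degenerate hierarchy collapses all countries onto one trajectory", {
  spec <- generator_spec(n_countries = 5, sigma_alpha = 0, sigma_beta = 0,
                         gamma_sdi = 0, gamma_hrh = 0, seed = 2)
  truth <- generate_trajectories(spec)
  nat <- dplyr::filter(truth$truth, stratum == "national") |>
    tidyr::pivot_wider(id_cols = "year", names_from = "country_iso",
                       values_from = "p_true")
  surfaces <- as.matrix(nat[, -1])
  expect_true(all(abs(surfaces - surfaces[, 1]) < 1e-12))
})

test_that("urban and rural surfaces coincide when the urban advantage is zero", {
  spec <- generator_spec(n_countries = 3, urban_advantage = 0, seed = 4)
  truth <- generate_trajectories(spec)
  wide <- dplyr::filter(truth$truth, stratum %in% c("urban", "rural")) |>
    tidyr::pivot_wider(id_cols = c("country_iso", "year"),
                       names_from = "stratum", values_from = "p_true")
  expect_equal(wide$urban, wide$rural)
})

test_that("quintile surfaces are monotone when the gradient is positive", {
  spec <- generator_spec(n_countries = 3, quintile_gradient = 0.4, seed = 6)
  truth <- generate_trajectories(spec)
  q <- dplyr::filter(truth$truth, stratum %in% paste0("Q", 1:5)) |>
    tidyr::pivot_wider(id_cols = c("country_iso", "year"),
                       names_from = "stratum", values_from = "p_true")
  expect_true(all(q$Q1 < q$Q2 & q$Q2 < q$Q3 & q$Q3 < q$Q4 & q$Q4 < q$Q5))
})

test_that("the default spec yields the documented survey bookkeeping", {
  spec <- generator_spec(seed = 3)
  expect_equal(spec$n_countries, 54L)
  expect_equal(spec$surveys_per_country, 4L)
  truth <- generate_trajectories(spec)
  sv <- generate_surveys(truth, spec)
  expect_gte(nrow(sv), 216)
  expect_lte(nrow(sv), 224)
  expect_equal(unique(sv$source), "SYNTH")
  expect_true(all(sv$survey_year >= 2000 & sv$survey_year <= 2019))
  expect_equal(unique(sv$n_effective),
               spec$n_respondents / spec$design_effect)
  expect_setequal(unique(sv$region), lmic_regions())
})

test_that("huge samples concentrate observed coverage at the truth", {
  spec <- generator_spec(n_countries = 2, surveys_per_country = 2,
                         n_respondents = 2e6, design_effect = 2, seed = 8)
  truth <- generate_trajectories(spec)
  sv <- generate_surveys(truth, spec)
  joined <- dplyr::inner_join(
    sv, truth$truth,
    by = c("country_iso", "stratum", "survey_year" = "year"))
  expect_true(all(abs(joined$coverage - joined$p_true) < 0.005))
})

test_that("survey noise has the binomial standard deviation", {
  # 250 countries x 4 surveys at p* = 0.5 and n_eff = 100 give 1,000
  # independent binomial proportions whose SD should be near 0.05
  spec <- generator_spec(n_countries = 250, sigma_alpha = 0, sigma_beta = 0,
                         mu_alpha = 0, mu_beta = 0, gamma_sdi = 0,
                         gamma_hrh = 0, n_respondents = 200,
                         design_effect = 2, seed = 10)
  truth <- generate_trajectories(spec)
  sv <- generate_surveys(truth, spec)
  expect_equal(nrow(sv), 1000)
  expect_equal(sd(sv$coverage), 0.05, tolerance = 0.15)
})

test_that("null individual effects give 50% prevalence and a known OR is reproduced", {
  null_truth <- list(intercept = 0,
                     coefficients = setNames(
                       rep(0, 21), names(default_determinant_truth()$coefficients)),
                     sigma2_u0 = 0)
  spec <- generator_spec(n_countries = 5, determinant_truth = null_truth,
                         seed = 14)
  rec <- generate_individuals(spec, n_per_country = 10000)
  expect_equal(mean(rec$outcome_insd), 0.5, tolerance = 0.02)

  or_truth <- null_truth
  or_truth$coefficients["residence:rural"] <- log(2)
  spec2 <- generator_spec(n_countries = 5, determinant_truth = or_truth,
                          seed = 15)
  rec2 <- generate_individuals(spec2, n_per_country = 10000)
  tab <- table(rec2$residence, rec2$outcome_insd)
  emp_or <- (tab["rural", "1"] / tab["rural", "0"]) /
    (tab["urban", "1"] / tab["urban", "0"])
  expect_equal(emp_or, 2, tolerance = 0.1)
})

test_that("synthetic outputs carry a provenance sidecar", {
  spec <- generator_spec(n_countries = 2, seed = 44)
  truth <- generate_trajectories(spec)
  sv <- generate_surveys(truth, spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_synthetic(sv, path, spec)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 44)
  expect_equal(meta$n_countries, 2)
  expect_equal(nrow(read_survey_points(path)), nrow(sv))
})
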