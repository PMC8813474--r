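#' Specification of the synthetic study generator
#'
#' Describes a synthetic multi-country survey study with known ground
#' truth: country log-odds intercepts and decade slopes drawn from the
#' hierarchical trend model's hyper-distributions, smooth increasing
#' SDI/HRH covariate series, logit-scale urban/rural and wealth-quintile
#' offsets, binomial survey sampling with a design effect, and an
#' individual-level outcome model for the determinants analysis. The
#' defaults emulate the structure of the real study: 54 countries in 6
#' regions surveyed about 4 times each over 2000-2019 with roughly 2,000
#' adolescent births per survey and a design effect of 2.
#'
#' @param n_countries,n_regions Number of countries and regions (regions
#'   are assigned round-robin from [lmic_regions()]).
#' @param years_observed Observation window for surveys.
#' @param surveys_per_country Surveys scheduled per country, evenly spaced
#'   with seed-jitter across the window.
#' @param mu_alpha,sigma_alpha Hyper-mean/SD of country intercepts
#'   (log-odds at 2000).
#' @param mu_beta,sigma_beta Hyper-mean/SD of country slopes (log-odds per
#'   decade).
#' @param gamma_sdi,gamma_hrh Covariate effects on the natural (raw)
#'   scales of SDI and HRH.
#' @param design_effect Cluster-survey variance inflation.
#' @param n_respondents Raw respondents per survey; the binomial
#'   denominator is `n_respondents / design_effect`.
#' @param urban_advantage Logit offset between urban and rural
#'   (urban = national + half, rural = national - half).
#' @param quintile_gradient Logit increment per wealth quintile, centred
#'   on Q3.
#' @param determinant_truth Named list with `intercept`, `coefficients`
#'   (named log-odds for every non-reference level, in
#'   [encode_design()] column naming) and `sigma2_u0`.
#' @param seed Integer seed recorded in all outputs.
#' @return A validated list of class `generator_spec`.
#' @export
#' @examples
#' generator_spec(n_countries = 10, seed = 3)
generator_spec <- function(n_countries = 54, n_regions = 6,
                           years_observed = 2000:2019,
                           surveys_per_country = 4,
                           mu_alpha = -0.5, sigma_alpha = 1.5,
                           mu_beta = 1.0, sigma_beta = 0.6,
                           gamma_sdi = 1.0, gamma_hrh = 0.2,
                           design_effect = 2, n_respondents = 2000,
                           urban_advantage = 0.8, quintile_gradient = 0.4,
                           determinant_truth = default_determinant_truth(),
                           seed = 1) {
  stopifnot(n_countries >= 1, n_regions >= 1, n_regions <= 6,
            surveys_per_country >= 1, sigma_alpha >= 0, sigma_beta >= 0,
            design_effect >= 1, n_respondents > 0, urban_advantage >= 0,
            determinant_truth$sigma2_u0 >= 0)
  structure(list(
    n_countries = as.integer(n_countries), n_regions = as.integer(n_regions),
    years_observed = as.integer(years_observed),
    surveys_per_country = as.integer(surveys_per_country),
    mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
    mu_beta = mu_beta, sigma_beta = sigma_beta,
    gamma_sdi = gamma_sdi, gamma_hrh = gamma_hrh,
    design_effect = design_effect, n_respondents = n_respondents,
    urban_advantage = urban_advantage, quintile_gradient = quintile_gradient,
    determinant_truth = determinant_truth, seed = as.integer(seed)
  ), class = "generator_spec")
}

#' Default ground truth for the individual-level outcome model
#'
#' Moderate log-odds effects in the directions reported for delivery-care
#' determinants (higher education, antenatal contact, media access and
#' wealth raise the odds; higher parity and rural residence lower them),
#' with a between-country intercept variance of 1.5.
#'
#' @return A list with `intercept`, named `coefficients` and `sigma2_u0`.
#' @export
default_determinant_truth <- function() {
  list(
    intercept = 0,
    coefficients = c(
      "hh_head_age:30-45" = 0.00, "hh_head_age:46-60" = 0.10,
      "hh_head_age:>60" = 0.15,
      "hh_head_sex:female" = 0.15,
      "education:primary" = 0.25, "education:secondary" = 0.60,
      "education:higher" = 0.95,
      "parity:2" = -0.50, "parity:3" = -0.75, "parity:>=4" = -0.67,
      "anc_visits:1" = 0.75, "anc_visits:2" = 1.05, "anc_visits:3" = 1.35,
      "anc_visits:>=4" = 1.77,
      "media:<weekly" = 0.10, "media:>=weekly" = 0.26,
      "wealth_quintile:Q2" = 0.28, "wealth_quintile:Q3" = 0.55,
      "wealth_quintile:Q4" = 0.90, "wealth_quintile:Q5" = 1.30,
      "residence:rural" = -0.40
    ),
    sigma2_u0 = 1.5
  )
}

# documented covariate marginals for synthetic individuals
.individual_marginals <- function() {
  list(
    hh_head_age = c(0.35, 0.40, 0.17, 0.08),
    hh_head_sex = c(0.78, 0.22),
    education = c(0.25, 0.35, 0.30, 0.10),
    parity = c(0.65, 0.25, 0.07, 0.03),
    anc_visits = c(0.15, 0.10, 0.12, 0.15, 0.48),
    media = c(0.30, 0.25, 0.45),
    wealth_quintile = rep(0.2, 5),
    residence = c(0.35, 0.65)
  )
}

.synth_countries <- function(spec) {
  sprintf("S%02d", seq_len(spec$n_countries))
}

.synth_regions <- function(spec) {
  lmic_regions()[(seq_len(spec$n_countries) - 1L) %% spec$n_regions + 1L]
}

#' Generate the true coverage surface and covariate series
#'
#' Draws country intercepts and slopes from the spec's hyper-distributions,
#' simulates smooth increasing SDI (concave, in \[0, 1\]) and HRH (convex,
#' positive) series for 2000-2030, and evaluates the true coverage
#' p\*(country, year, stratum) on the logit scale with the urban/rural and
#' quintile offsets applied around the national value.
#'
#' @param spec A [generator_spec()].
#' @return A list of class `synthetic_truth`: `truth` (tibble of
#'   `country_iso`, `region`, `year`, `stratum`, `p_true`), `params`
#'   (country intercepts/slopes), `covariates`, and the `spec`.
#' @export
generate_trajectories <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  countries <- .synth_countries(spec)
  regions <- .synth_regions(spec)
  k <- spec$n_countries
  alpha <- rnorm(k, spec$mu_alpha, spec$sigma_alpha)
  beta <- rnorm(k, spec$mu_beta, spec$sigma_beta)
  years <- seq(min(spec$years_observed), 2030L)

  # smooth increasing covariate series with country-specific level, gain
  # and curvature, so development paths differ in shape across countries
  sdi_start <- runif(k, 0.2, 0.6)
  sdi_gain <- runif(k, 0.05, 0.35)
  sdi_shape <- runif(k, 0.4, 1.6)
  hrh_start <- runif(k, 0.5, 3.0)
  hrh_gain <- runif(k, 0.2, 4.0)
  hrh_shape <- runif(k, 0.4, 1.6)
  covariates <- tidyr::expand_grid(country_iso = countries, year = years) |>
    dplyr::mutate(
      idx = match(.data$country_iso, countries),
      frac = (.data$year - min(years)) / (2030 - min(years)),
      sdi = pmin(sdi_start[.data$idx] +
                   sdi_gain[.data$idx] * .data$frac^sdi_shape[.data$idx], 1),
      hrh = hrh_start[.data$idx] +
        hrh_gain[.data$idx] * .data$frac^hrh_shape[.data$idx]
    ) |>
    dplyr::select("country_iso", "year", "sdi", "hrh")

  strata <- coverage_strata()
  offsets <- c(national = 0,
               urban = spec$urban_advantage / 2,
               rural = -spec$urban_advantage / 2,
               setNames(spec$quintile_gradient * (1:5 - 3), paste0("Q", 1:5)))
  truth <- tidyr::expand_grid(country_iso = countries, year = years,
                              stratum = strata) |>
    dplyr::left_join(covariates, by = c("country_iso", "year")) |>
    dplyr::mutate(
      idx = match(.data$country_iso, countries),
      region = regions[.data$idx],
      eta = alpha[.data$idx] + beta[.data$idx] * .time_decade(.data$year) +
        spec$gamma_sdi * .data$sdi + spec$gamma_hrh * .data$hrh +
        offsets[.data$stratum],
      p_true = inv_logit(.data$eta)
    ) |>
    dplyr::select("country_iso", "region", "year", "stratum", "p_true")

  structure(list(
    truth = truth,
    params = tibble::tibble(country_iso = countries, region = regions,
                            alpha = alpha, beta = beta),
    covariates = covariates, spec = spec
  ), class = "synthetic_truth")
}

# evenly spaced survey years with seed-jitter, kept unique within country
.survey_years <- function(spec) {
  yrs <- range(spec$years_observed)
  m <- spec$surveys_per_country
  base <- round(seq(yrs[1], yrs[2], length.out = m))
  jit <- sample(-1:1, m, replace = TRUE)
  out <- pmin(pmax(base + jit, yrs[1]), yrs[2])
  while (anyDuplicated(out)) {
    d <- which(duplicated(out))[1]
    out[d] <- if (out[d] < yrs[2]) out[d] + 1L else out[d] - m
    out <- pmin(pmax(out, yrs[1]), yrs[2])
  }
  sort(as.integer(out))
}

#' Draw binomial survey points from the true surface
#'
#' Schedules `surveys_per_country` surveys per country and, for each, draws
#' observed successes from Binomial(n_effective, p\*) with
#' n_effective = n_respondents / design_effect.
#'
#' @param truth A `synthetic_truth` from [generate_trajectories()].
#' @param spec The same [generator_spec()].
#' @param strata Strata to observe (default national only).
#' @param outcome Outcome label stamped on the points.
#' @return A validated survey-point tibble (`source = "SYNTH"`).
#' @export
generate_surveys <- function(truth, spec, strata = "national",
                             outcome = "INSD") {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(spec$seed + 1L)
  n_eff <- round(spec$n_respondents / spec$design_effect)
  countries <- .synth_countries(spec)
  schedule <- purrr::map(countries, function(cc) {
    tibble::tibble(country_iso = cc, survey_year = .survey_years(spec))
  }) |> dplyr::bind_rows()
  pts <- tidyr::expand_grid(schedule, stratum = strata) |>
    dplyr::inner_join(truth$truth,
                      by = c("country_iso", "stratum", "survey_year" = "year")) |>
    dplyr::mutate(
      successes = rbinom(dplyr::n(), n_eff, .data$p_true),
      coverage = .data$successes / n_eff,
      n_effective = n_eff,
      source = "SYNTH", outcome = !!outcome
    ) |>
    dplyr::select("country_iso", "region", "survey_year", "source",
                  "stratum", "outcome", "coverage", "n_effective")
  validate_survey_points(pts)
}

#' Generate individual-level records with known determinant effects
#'
#' Covariates are drawn from fixed documented marginal distributions;
#' country intercepts u_i from Normal(0, sigma2_u0); each outcome from
#' Bernoulli(inv_logit(intercept + u_i + x'b_true)). The institutional
#' delivery and skilled-attendance outcomes share the covariate effects,
#' the latter with a +0.3 logit offset.
#'
#' @param spec A [generator_spec()] (its `determinant_truth` is the ground
#'   truth).
#' @param n_per_country Records per country.
#' @return A validated individual-record tibble; the drawn country
#'   intercepts are attached as the `u_true` attribute.
#' @export
generate_individuals <- function(spec, n_per_country = 2000) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed + 2L)
  countries <- .synth_countries(spec)
  n <- spec$n_countries * n_per_country
  tr <- spec$determinant_truth
  # country effects drawn first so they do not depend on n_per_country
  u <- rnorm(spec$n_countries, 0, sqrt(tr$sigma2_u0))
  lv <- individual_levels()
  marg <- .individual_marginals()
  records <- tibble::tibble(
    country_iso = rep(countries, each = n_per_country)
  )
  for (v in names(lv)) {
    records[[v]] <- sample(lv[[v]], n, replace = TRUE, prob = marg[[v]])
  }
  design <- local({
    # encode without outcomes present yet
    tmp <- records
    tmp$outcome_insd <- 0L
    tmp$outcome_sba <- 0L
    encode_design(tmp)
  })
  b <- tr$coefficients[design$columns]
  if (anyNA(b)) {
    abort(paste0("determinant_truth$coefficients must name every design column; missing: ",
                 paste(setdiff(design$columns, names(tr$coefficients)),
                       collapse = ", ")))
  }
  eta <- tr$intercept + u[match(records$country_iso, countries)] +
    as.vector(design$x %*% b)
  records$outcome_insd <- rbinom(n, 1, inv_logit(eta))
  records$outcome_sba <- rbinom(n, 1, inv_logit(eta + 0.3))
  out <- validate_individuals(records)
  attr(out, "u_true") <- setNames(u, countries)
  out
}

#' Write a generated table with a provenance sidecar
#'
#' Writes the CSV plus a `<path>.meta.json` sidecar recording the full
#' generator spec (including the seed).
#'
#' @param x A tibble produced by one of the generators.
#' @param path Output CSV path.
#' @param spec The [generator_spec()] that produced it.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(x, path, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  readr::write_csv(x, path)
  jsonlite::write_json(unclass(spec), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
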