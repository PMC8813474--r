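#' Posterior coverage draws for country-years
#'
#' For each retained draw, coverage is the inverse logit of the draw's
#' linear predictor at the requested year, using the covariate scaling
#' stored in the fit. Returns draws on the percent scale.
#'
#' @param fit A `trend_fit`.
#' @param covariates Covariate series covering the requested years for every
#'   modelled country; defaults to the series stored in the fit.
#' @param years Years to evaluate.
#' @param extrapolate If the series stops before the last requested year,
#'   extend it with [extrapolate_covariates()] (off by default; missing
#'   years are then an error).
#' @return A list with `draws` (matrix, total draws x country-years) and a
#'   `grid` tibble describing its columns.
#' @export
coverage_draws <- function(fit, covariates = NULL, years = 2000:2030,
                           extrapolate = FALSE) {
  years <- as.integer(years)
  use_cov <- fit$config$use_covariates
  if (use_cov) {
    covariates <- validate_covariates(covariates %||% fit$covariates)
    if (extrapolate) covariates <- extrapolate_covariates(covariates, max(years))
  }
  grid <- tidyr::expand_grid(country_iso = fit$countries, year = years)
  if (use_cov) {
    grid <- dplyr::left_join(grid, covariates, by = c("country_iso", "year"))
    if (anyNA(grid$sdi) || anyNA(grid$hrh)) {
      miss <- grid[is.na(grid$sdi) | is.na(grid$hrh), ]
      abort(paste0(
        "missing projection-year covariates (extrapolation disabled): ",
        paste(head(paste(miss$country_iso, miss$year), 8), collapse = ", "),
        if (nrow(miss) > 8) ", ..." else ""))
    }
    zs <- (grid$sdi - fit$cov_scaling$center["sdi"]) / fit$cov_scaling$scale["sdi"]
    zh <- (grid$hrh - fit$cov_scaling$center["hrh"]) / fit$cov_scaling$scale["hrh"]
  } else {
    zs <- zh <- numeric(nrow(grid))
  }
  all_draws <- do.call(rbind, fit$chains)
  a <- all_draws[, paste0("alpha[", grid$country_iso, "]"), drop = FALSE]
  b <- all_draws[, paste0("beta[", grid$country_iso, "]"), drop = FALSE]
  eta <- a + b * rep(.time_decade(grid$year), each = nrow(all_draws))
  if (use_cov) {
    eta <- eta + outer(all_draws[, "gamma_sdi"], zs) +
      outer(all_draws[, "gamma_hrh"], zh)
  }
  list(draws = 100 * inv_logit(eta), grid = grid[, c("country_iso", "year")])
}

#' Project coverage trajectories with credible intervals
#'
#' Summarises the posterior coverage draws of a fitted trend model into a
#' trajectory table: for every country-year the posterior mean and the
#' 2.5th/97.5th percentile bounds of coverage, in percent.
#'
#' @inheritParams coverage_draws
#' @return A tibble with columns `country_iso`, `stratum`, `outcome`,
#'   `year`, `mean`, `cri_low`, `cri_high` (percent).
#' @export
#' @examples
#' spec <- generator_spec(n_countries = 3, surveys_per_country = 4, seed = 42)
#' truth <- generate_trajectories(spec)
#' fit <- fit_trend(generate_surveys(truth, spec), truth$covariates,
#'                  mcmc_config(n_iter = 600, burn_in = 100, thin = 2, seed = 1))
#' project_coverage(fit, years = c(2000, 2018, 2030))
project_coverage <- function(fit, covariates = NULL, years = 2000:2030,
                             extrapolate = FALSE) {
  cd <- coverage_draws(fit, covariates, years, extrapolate)
  q <- apply(cd$draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  dplyr::mutate(cd$grid,
                stratum = fit$stratum, outcome = fit$outcome,
                mean = colMeans(cd$draws),
                cri_low = q[1, ], cri_high = q[2, ],
                .after = "country_iso") |>
    dplyr::relocate("year", .after = "outcome")
}

#' Write a trajectory table to CSV
#'
#' @param trajectories A tibble from [project_coverage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  readr::write_csv(trajectories, path)
  invisible(path)
}

#' Linearly extend covariate series to a horizon year
#'
#' Each country's SDI and HRH are extended by a straight line fitted to its
#' last (up to) 10 observed years, with SDI clipped to \[0, 1\] and HRH to
#' non-negative values.
#'
#' @param covariates A validated covariate series.
#' @param to Horizon year.
#' @return The extended, validated series.
#' @export
extrapolate_covariates <- function(covariates, to = 2030) {
  covariates <- validate_covariates(covariates)
  ext <- split(covariates, covariates$country_iso) |>
    purrr::map(function(cc) {
      last <- max(cc$year)
      if (last >= to) return(NULL)
      base <- dplyr::filter(cc, .data$year > last - 10)
      yrs <- seq(last + 1L, as.integer(to))
      pred <- function(v) {
        if (nrow(base) < 2) return(rep(base[[v]][1], length(yrs)))
        unname(stats::predict(lm(stats::reformulate("year", v), base),
                              tibble::tibble(year = yrs)))
      }
      tibble::tibble(country_iso = cc$country_iso[1], year = yrs,
                     sdi = pmin(pmax(pred("sdi"), 0), 1),
                     hrh = pmax(pred("hrh"), 0))
    }) |>
    dplyr::bind_rows()
  validate_covariates(dplyr::bind_rows(covariates, ext)) |>
    dplyr::arrange(.data$country_iso, .data$year)
}

#' Median absolute difference between two trajectory tables
#'
#' The summary statistic of the sensitivity protocol: trajectories are
#' matched on country, stratum, outcome and year, and the median of
#' |mean_a - mean_b| is reported per year (percentage points).
#'
#' @param a,b Trajectory tibbles from [project_coverage()].
#' @return A tibble with columns `year`, `median_abs_diff`.
#' @export
trajectory_difference <- function(a, b) {
  joined <- dplyr::inner_join(
    a, b, by = c("country_iso", "stratum", "outcome", "year"),
    suffix = c("_a", "_b")
  )
  if (nrow(joined) == 0) abort("trajectories share no country-year cells")
  dplyr::summarise(joined,
                   median_abs_diff = median(abs(.data$mean_a - .data$mean_b)),
                   .by = "year") |>
    dplyr::arrange(.data$year)
}

#' Sensitivity protocol: covariate exclusion and alternate priors
#'
#' Refits the trend model (a) without the country-level covariates and
#' (b) with an alternate prior family on the hierarchical SDs, and reports
#' the median absolute difference of posterior-mean coverage against the
#' base fit, per year.
#'
#' @param data,covariates,config As in [fit_trend()].
#' @param years Years at which trajectories are compared.
#' @param alt_prior_family,alt_prior_scale The alternate hyper-SD prior
#'   (default uniform(0, 10)).
#' @return An object of class `sensitivity_report`: the three trajectory
#'   tables and a `differences` tibble with columns `comparison`, `year`,
#'   `median_abs_diff`.
#' @export
sensitivity_refit <- function(data, covariates = NULL, config = mcmc_config(),
                              years = 2000:2030,
                              alt_prior_family = "uniform",
                              alt_prior_scale = 10) {
  base_fit <- fit_trend(data, covariates, config)
  base_traj <- project_coverage(base_fit, years = years)

  cfg_nc <- config
  cfg_nc$use_covariates <- FALSE
  traj_nc <- project_coverage(fit_trend(data, covariates = NULL, cfg_nc),
                              years = years)

  cfg_ap <- config
  cfg_ap$prior_family_sd <- alt_prior_family
  cfg_ap$prior_scale_sd <- alt_prior_scale
  traj_ap <- project_coverage(fit_trend(data, covariates, cfg_ap),
                              years = years)

  differences <- dplyr::bind_rows(
    dplyr::mutate(trajectory_difference(base_traj, traj_nc),
                  comparison = "no_covariates", .before = 1),
    dplyr::mutate(trajectory_difference(base_traj, traj_ap),
                  comparison = "alt_prior", .before = 1)
  )
  structure(list(base = base_traj, no_covariates = traj_nc,
                 alt_prior = traj_ap, differences = differences),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity protocol (median absolute difference of posterior means, %):\n")
  smry <- dplyr::summarise(x$differences,
                           max_median_abs_diff = max(.data$median_abs_diff),
                           .by = "comparison")
  print(smry)
  invisible(x)
}
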