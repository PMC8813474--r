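# small in-code fixtures shared across tests

make_survey_tbl <- function(country = "S01", years = c(2002L, 2008L, 2014L, 2018L),
                            coverage = c(0.2, 0.35, 0.5, 0.62),
                            n_effective = 1000, region = "South Asia",
                            stratum = "national", outcome = "INSD") {
  tibble::tibble(
    country_iso = country, region = region, survey_year = years,
    source = "SYNTH", stratum = stratum, outcome = outcome,
    coverage = coverage, n_effective = n_effective
  )
}

make_covariates_tbl <- function(countries = "S01", years = 2000:2030) {
  tidyr::expand_grid(country_iso = countries, year = as.integer(years)) |>
    dplyr::mutate(
      sdi = 0.3 + 0.3 * ((year - 2000) / 30)^0.8 +
        0.05 * (match(country_iso, unique(country_iso)) - 1),
      hrh = 1 + 2 * ((year - 2000) / 30)^1.2 +
        0.3 * (match(country_iso, unique(country_iso)) - 1)
    )
}

# a hand-built trend_fit with known draws, for projection identities
make_fake_trend_fit <- function(alpha_draws, beta_draws, country = "S01") {
  n <- length(alpha_draws)
  m <- cbind(alpha_draws, beta_draws, 0, 0, 0, 0, 1, 1, 0, 1)
  colnames(m) <- c(paste0("alpha[", country, "]"), paste0("beta[", country, "]"),
                   "gamma_sdi", "gamma_hrh", "mu_alpha", "mu_beta",
                   "sigma_alpha", "sigma_beta",
                   "mu_alpha_region[South Asia]", "sigma_mu_region")
  structure(list(
    chains = list(m), parameters = colnames(m),
    monitored = colnames(m)[1:2], countries = country,
    regions = "South Asia", region_of = "South Asia",
    config = suppressWarnings(
      mcmc_config(n_iter = n + 1, burn_in = 0, thin = 1, n_chains = 1,
                  use_covariates = FALSE)),
    cov_scaling = list(center = c(sdi = 0, hrh = 0),
                       scale = c(sdi = 1, hrh = 1)),
    covariates = NULL, outcome = "INSD", stratum = "national",
    n_obs = 0L, acceptance = tibble::tibble()
  ), class = "trend_fit")
}

# independent PSRF reference via the one-way ANOVA decomposition
psrf_anova_oracle <- function(chains) {
  y <- unlist(chains)
  g <- factor(rep(seq_along(chains), lengths(chains)))
  ms <- anova(lm(y ~ g))[["Mean Sq"]]
  n <- lengths(chains)[1]
  W <- ms[2]                # pooled within-chain variance
  B_over_n <- ms[1] / n     # MS between groups = n * var(chain means)
  sqrt((n - 1) / n + B_over_n / W)
}
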