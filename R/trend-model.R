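#' Logit and inverse-logit link
#'
#' The trend model is linear on the log-odds scale; these are its link and
#' inverse link. `logit()` is defined on the open interval (0, 1): observed
#' coverages of exactly 0 or 1 must first be pulled inside the interval
#' (see [clamp_coverage()]).
#'
#' @param p Proportions strictly between 0 and 1.
#' @param x Real numbers.
#' @return `logit()` returns log-odds; `inv_logit()` returns proportions in
#'   (0, 1).
#' @export
#' @examples
#' logit(0.8)
#' inv_logit(logit(0.8))
logit <- function(p) {
  if (any(p <= 0 | p >= 1)) {
    abort("logit() needs proportions strictly inside (0, 1); clamp boundary values first")
  }
  qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) plogis(x)

#' Pull boundary coverages inside (0, 1)
#'
#' Observed coverages of exactly 0 or 1 are clamped to
#' `[0.5/n_effective, 1 - 0.5/n_effective]` before any logit used in
#' initialisation. The binomial likelihood itself needs no clamp.
#'
#' @param coverage Observed proportions.
#' @param n_effective Effective sample sizes.
#' @return Clamped proportions.
#' @export
clamp_coverage <- function(coverage, n_effective) {
  pmin(pmax(coverage, 0.5 / n_effective), 1 - 0.5 / n_effective)
}

#' MCMC configuration for the hierarchical samplers
#'
#' The defaults reproduce the production sampling plan: 10,000 iterations,
#' three chains, thinning of 10 and a burn-in of 500, giving 950 retained
#' draws per chain. Priors are weakly informative: Normal(0, `prior_scale_fixed`^2)
#' on fixed effects and hyper-means, and a positive prior of family
#' `prior_family_sd` with scale `prior_scale_sd` on hierarchical SDs.
#'
#' @param n_iter Total iterations per chain.
#' @param n_chains Number of chains (at least 2 for convergence diagnostics).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param burn_in Discarded initial iterations (proposal scales adapt only
#'   during burn-in and are frozen afterwards).
#' @param seed Integer seed; all chains derive their streams from it.
#' @param prior_scale_fixed SD of the normal prior on fixed effects and
#'   hyper-means (log-odds scale).
#' @param prior_family_sd Prior family for hierarchical SDs:
#'   `"half_cauchy"` (default), `"uniform"` or `"half_normal"`.
#' @param prior_scale_sd Scale of that prior.
#' @param use_covariates Include the SDI and HRH terms in the trend model.
#' @param region_hierarchy Add a region level above the country intercepts
#'   (region means drawn around a global mean); off by default.
#' @param hierarchical Partial-pool country intercepts/slopes; turning this
#'   off gives each country independent fixed priors (used for
#'   single-country checks).
#' @param fit_slope Estimate country time slopes; off fixes them at zero.
#' @param intercept_prior Prior on country intercepts when `hierarchical`
#'   is off: `"normal"` (Normal(0, `prior_scale_fixed`^2)) or `"logistic"`
#'   (standard logistic on the log-odds, i.e. uniform on the probability
#'   scale).
#' @return A validated list of class `mcmc_config`.
#' @export
#' @examples
#' mcmc_config(n_iter = 2000, burn_in = 200, thin = 2, seed = 7)
mcmc_config <- function(n_iter = 10000, n_chains = 3, thin = 10,
                        burn_in = 500, seed = 1,
                        prior_scale_fixed = 100,
                        prior_family_sd = c("half_cauchy", "uniform", "half_normal"),
                        prior_scale_sd = 2.5,
                        use_covariates = TRUE, region_hierarchy = FALSE,
                        hierarchical = TRUE, fit_slope = TRUE,
                        intercept_prior = c("normal", "logistic")) {
  prior_family_sd <- match.arg(prior_family_sd)
  intercept_prior <- match.arg(intercept_prior)
  stopifnot(n_iter > burn_in, burn_in >= 0, thin >= 1, n_chains >= 1,
            prior_scale_fixed > 0, prior_scale_sd > 0)
  if (n_chains < 2) {
    warn("fewer than 2 chains: Gelman-Rubin diagnostics unavailable")
  }
  structure(list(
    n_iter = as.integer(n_iter), n_chains = as.integer(n_chains),
    thin = as.integer(thin), burn_in = as.integer(burn_in),
    seed = as.integer(seed), prior_scale_fixed = prior_scale_fixed,
    prior_family_sd = prior_family_sd, prior_scale_sd = prior_scale_sd,
    use_covariates = isTRUE(use_covariates),
    region_hierarchy = isTRUE(region_hierarchy),
    hierarchical = isTRUE(hierarchical), fit_slope = isTRUE(fit_slope),
    intercept_prior = intercept_prior
  ), class = "mcmc_config")
}

#' Read an MCMC configuration from a YAML file
#'
#' Every field of [mcmc_config()] can be set by a top-level key of the same
#' name; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return An `mcmc_config` object.
#' @export
read_mcmc_config <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(mcmc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(mcmc_config, vals)
}

.sd_family_code <- function(family) {
  match(family, c("half_cauchy", "uniform", "half_normal")) - 1L
}

.sd_log_prior <- function(s, family, scale) {
  if (any(s <= 0)) return(-Inf)
  switch(family,
         half_cauchy = sum(-log1p((s / scale)^2)),
         uniform = if (all(s < scale)) 0 else -Inf,
         half_normal = sum(-0.5 * (s / scale)^2))
}

# decade-scaled model time
.time_decade <- function(year) (year - 2000) / 10

# join z-scored covariates onto survey rows; returns list(sdi, hrh) or zeros
.covariate_terms <- function(data, covariates, center, scale) {
  joined <- dplyr::left_join(
    data, covariates, by = c("country_iso", "survey_year" = "year")
  )
  if (anyNA(joined$sdi) || anyNA(joined$hrh)) {
    miss <- joined[is.na(joined$sdi) | is.na(joined$hrh),
                   c("country_iso", "survey_year")]
    abort(paste0("missing covariate rows for: ",
                 paste(paste(miss$country_iso, miss$survey_year), collapse = ", ")))
  }
  list(sdi = (joined$sdi - center["sdi"]) / scale["sdi"],
       hrh = (joined$hrh - center["hrh"]) / scale["hrh"])
}

#' Log posterior density of the trend model
#'
#' Pure-R reference implementation of the unnormalised log posterior the
#' sampler targets: a binomial likelihood on effective counts with
#' logit(p) = alpha_i + beta_i (t - 2000)/10 + gamma_sdi SDI + gamma_hrh HRH,
#' country intercepts and slopes drawn from Normal(mu, sigma^2)
#' hyper-distributions, normal priors on fixed effects and hyper-means and
#' the configured positive prior on hyper-SDs. Covariates enter z-scored
#' against the fitting set.
#'
#' @param params A list with elements `alpha` and `beta` (named by
#'   `country_iso`), `gamma_sdi`, `gamma_hrh`, `mu_alpha`, `mu_beta`,
#'   `sigma_alpha`, `sigma_beta`.
#' @param data A validated survey-point tibble (may have zero rows, in which
#'   case only the prior contributes).
#' @param covariates Covariate series covering every survey row (required
#'   when `config$use_covariates` is `TRUE` and `data` has rows).
#' @param config An [mcmc_config()].
#' @return The log posterior up to an additive constant.
#' @export
trend_log_posterior <- function(params, data, covariates = NULL,
                                config = mcmc_config()) {
  p <- params
  if (any(!is.finite(unlist(p[c("gamma_sdi", "gamma_hrh", "mu_alpha", "mu_beta")])))) {
    abort("non-finite parameter values")
  }
  if (p$sigma_alpha <= 0 || p$sigma_beta <= 0) return(-Inf)
  pf <- config$prior_scale_fixed
  lp <- sum(dnorm(c(p$mu_alpha, p$mu_beta, p$gamma_sdi, p$gamma_hrh),
                  0, pf, log = TRUE))
  lp <- lp + .sd_log_prior(c(p$sigma_alpha, p$sigma_beta),
                           config$prior_family_sd, config$prior_scale_sd)
  if (config$hierarchical) {
    lp <- lp + sum(dnorm(p$alpha, p$mu_alpha, p$sigma_alpha, log = TRUE)) +
      sum(dnorm(p$beta, p$mu_beta, p$sigma_beta, log = TRUE))
  } else if (config$intercept_prior == "logistic") {
    lp <- lp + sum(stats::dlogis(p$alpha, log = TRUE)) +
      sum(dnorm(p$beta, 0, pf, log = TRUE))
  } else {
    lp <- lp + sum(dnorm(c(p$alpha, p$beta), 0, pf, log = TRUE))
  }
  if (nrow(data) == 0) return(lp)
  data <- validate_survey_points(data)
  eta <- p$alpha[data$country_iso] + p$beta[data$country_iso] *
    .time_decade(data$survey_year)
  if (config$use_covariates) {
    if (is.null(covariates)) abort("covariates required when use_covariates is on")
    covariates <- validate_covariates(covariates)
    z <- .fit_cov_scaling(data, covariates)
    ct <- .covariate_terms(data, covariates, z$center, z$scale)
    eta <- eta + p$gamma_sdi * ct$sdi + p$gamma_hrh * ct$hrh
  }
  y <- data$coverage * data$n_effective
  lp + sum(y * eta - data$n_effective * log1p(exp(pmin(eta, 35))) -
             data$n_effective * pmax(eta - 35, 0))
}

# covariate standardisation against the fitting set (survey rows used)
.fit_cov_scaling <- function(data, covariates) {
  joined <- dplyr::inner_join(
    data, covariates, by = c("country_iso", "survey_year" = "year")
  )
  center <- c(sdi = mean(joined$sdi), hrh = mean(joined$hrh))
  scale <- c(sdi = sd(joined$sdi), hrh = sd(joined$hrh))
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

# per-country least-squares projection of each z-scored covariate onto
# (1, time): the compensating directions used by the sampler's shear moves
.cov_projection <- function(ci, td, ct, k, fit_slope) {
  proj_a <- matrix(0, k, 2)
  proj_b <- matrix(0, k, 2)
  for (i in seq_len(k)) {
    idx <- which(ci == i - 1L)
    if (length(idx) == 0) next
    for (j in 1:2) {
      z <- if (j == 1) ct$sdi[idx] else ct$hrh[idx]
      if (fit_slope && length(unique(td[idx])) >= 2) {
        cf <- coef(lm(z ~ td[idx]))
        proj_a[i, j] <- cf[1]
        proj_b[i, j] <- cf[2]
      } else {
        proj_a[i, j] <- mean(z)
      }
    }
  }
  list(a = proj_a, b = proj_b)
}

# data-informed starting values: per-country empirical-logit regression
.trend_inits <- function(data, countries) {
  l <- logit(clamp_coverage(data$coverage, data$n_effective))
  td <- .time_decade(data$survey_year)
  per <- lapply(countries, function(cc) {
    idx <- which(data$country_iso == cc)
    if (length(idx) == 0) return(c(NA_real_, NA_real_))
    if (length(idx) == 1 || length(unique(td[idx])) == 1) {
      return(c(mean(l[idx]), NA_real_))
    }
    unname(coef(lm(l[idx] ~ td[idx])))
  })
  alpha0 <- vapply(per, `[`, numeric(1), 1)
  beta0 <- vapply(per, `[`, numeric(1), 2)
  mean_beta <- mean(beta0, na.rm = TRUE)
  if (!is.finite(mean_beta)) mean_beta <- 0
  beta0[!is.finite(beta0)] <- mean_beta
  alpha0[!is.finite(alpha0)] <- mean(alpha0, na.rm = TRUE)
  alpha0[!is.finite(alpha0)] <- 0
  list(alpha = alpha0, beta = beta0)
}

#' Fit the hierarchical coverage trend model
#'
#' Runs an adaptive Metropolis-within-Gibbs sampler on the binomial-logit
#' trend model for one outcome and one stratum: country random intercepts
#' and decade slopes around hyper-means, optional z-scored SDI/HRH effects,
#' and the priors configured in [mcmc_config()]. Hyper-means are updated by
#' conjugate Gibbs steps; all other blocks by adaptive random-walk
#' proposals frozen at the end of burn-in. Fits are seed-deterministic.
#'
#' @param data A survey-point tibble for a single outcome and stratum.
#' @param covariates Country-year covariate series covering every survey
#'   row (only needed when `config$use_covariates`).
#' @param config An [mcmc_config()].
#' @param countries Optional character vector of countries to model;
#'   defaults to those present in `data`. Countries without survey rows get
#'   prior-only (shrunk) posteriors.
#' @return An object of class `trend_fit`: retained draws per chain,
#'   acceptance rates, the covariate scaling, and a Gelman-Rubin
#'   convergence report (see [psrf_table()]).
#' @export
#' @examples
#' spec <- generator_spec(n_countries = 3, surveys_per_country = 4, seed = 42)
#' truth <- generate_trajectories(spec)
#' surveys <- generate_surveys(truth, spec)
#' fit <- fit_trend(surveys, truth$covariates,
#'                  mcmc_config(n_iter = 600, burn_in = 100, thin = 2, seed = 1))
#' glance(fit)
fit_trend <- function(data, covariates = NULL, config = mcmc_config(),
                      countries = NULL) {
  data <- validate_survey_points(data)
  if (nrow(data) == 0) abort("at least one survey point is required")
  if (dplyr::n_distinct(data$outcome) > 1 || dplyr::n_distinct(data$stratum) > 1) {
    abort("fit_trend() models one outcome and one stratum at a time; filter or use fit_trend_strata()")
  }
  if (is.null(countries)) countries <- sort(unique(data$country_iso))
  if (!all(data$country_iso %in% countries)) {
    abort("`countries` must include every country present in the data")
  }
  region_of <- data$region[match(countries, data$country_iso)]
  region_of[is.na(region_of)] <- lmic_regions()[1]
  regions <- unique(region_of)

  ci <- match(data$country_iso, countries) - 1L
  td <- .time_decade(data$survey_year)
  y <- data$coverage * data$n_effective

  if (config$use_covariates) {
    if (is.null(covariates)) abort("covariates required when use_covariates is on")
    covariates <- validate_covariates(covariates)
    z <- .fit_cov_scaling(data, covariates)
    ct <- .covariate_terms(data, covariates, z$center, z$scale)
  } else {
    z <- list(center = c(sdi = 0, hrh = 0), scale = c(sdi = 1, hrh = 1))
    ct <- list(sdi = numeric(nrow(data)), hrh = numeric(nrow(data)))
  }

  inits <- .trend_inits(data, countries)
  k <- length(countries)
  proj <- .cov_projection(ci, td, ct, k, config$fit_slope)
  par_names <- c(paste0("alpha[", countries, "]"),
                 paste0("beta[", countries, "]"),
                 "gamma_sdi", "gamma_hrh", "mu_alpha", "mu_beta",
                 "sigma_alpha", "sigma_beta",
                 paste0("mu_alpha_region[", regions, "]"), "sigma_mu_region")

  chains <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * (ch - 1L))
    a0 <- inits$alpha + rnorm(k, 0, 0.1 * ch)
    b0 <- if (config$fit_slope) inits$beta + rnorm(k, 0, 0.1 * ch) else rep(0, k)
    sig_a0 <- max(sd(inits$alpha), 0.2)
    if (!is.finite(sig_a0)) sig_a0 <- 0.5
    sig_b0 <- max(sd(inits$beta), 0.2)
    if (!is.finite(sig_b0)) sig_b0 <- 0.5
    res <- .trend_chain_cpp(
      y, data$n_effective, ci, td, ct$sdi, ct$hrh, proj$a, proj$b,
      k, match(region_of, regions) - 1L, length(regions),
      a0, b0, 0, 0, mean(a0), mean(b0), sig_a0, sig_b0,
      config$use_covariates, config$hierarchical, config$fit_slope,
      config$region_hierarchy,
      if (config$intercept_prior == "logistic") 1L else 0L,
      config$prior_scale_fixed, .sd_family_code(config$prior_family_sd),
      config$prior_scale_sd,
      config$n_iter, config$burn_in, config$thin
    )
    colnames(res$draws) <- par_names
    chains[[ch]] <- res$draws
    accept[[ch]] <- tibble::tibble(
      parameter = c(paste0("alpha[", countries, "]"),
                    paste0("beta[", countries, "]"),
                    "gamma_sdi", "gamma_hrh", "sigma_alpha", "sigma_beta"),
      chain = ch,
      acceptance = c(res$accept_alpha, res$accept_beta,
                     res$accept_gamma, res$accept_sigma)
    )
  }

  monitored <- c(paste0("alpha[", countries, "]"),
                 if (config$fit_slope) paste0("beta[", countries, "]"),
                 if (config$use_covariates) c("gamma_sdi", "gamma_hrh"),
                 if (config$hierarchical) c("mu_alpha", "mu_beta",
                                            "sigma_alpha", "sigma_beta"))
  fit <- structure(list(
    chains = chains, parameters = par_names, monitored = monitored,
    countries = countries, regions = regions, region_of = region_of,
    config = config, cov_scaling = z, covariates = covariates,
    outcome = data$outcome[1], stratum = data$stratum[1],
    n_obs = nrow(data), acceptance = dplyr::bind_rows(accept)
  ), class = "trend_fit")
  fit$diagnostics <- if (config$n_chains >= 2) psrf_table(fit) else NULL
  fit
}

#' Fit the trend model independently within each stratum
#'
#' Urban/rural and wealth-quintile estimates use the same national model
#' fitted separately per stratum, with no cross-stratum constraint.
#'
#' @inheritParams fit_trend
#' @param data Survey points for one outcome, several strata.
#' @return A named list of `trend_fit` objects, one per stratum.
#' @export
fit_trend_strata <- function(data, covariates = NULL, config = mcmc_config()) {
  data <- validate_survey_points(data)
  split(data, data$stratum) |>
    purrr::map(~ fit_trend(.x, covariates, config))
}

#' Stacked posterior draws of a fitted model
#'
#' @param fit A `trend_fit` or `determinant_fit` object.
#' @param parameters Optional subset of parameter names.
#' @return A tibble with columns `chain`, `iteration`, `parameter`, `value`.
#' @export
posterior_draws <- function(fit, parameters = NULL) {
  purrr::imap(fit$chains, function(m, ch) {
    tibble::tibble(chain = as.integer(ch),
                   iteration = rep(seq_len(nrow(m)), ncol(m)),
                   parameter = rep(colnames(m), each = nrow(m)),
                   value = as.vector(m))
  }) |>
    dplyr::bind_rows() |>
    (\(d) if (is.null(parameters)) d else
      dplyr::filter(d, .data$parameter %in% parameters))()
}

#' Persist posterior draws to a long-format CSV
#'
#' @param fit A fitted model object.
#' @param path Output CSV path (`chain`, `iteration`, `parameter`, `value`).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  readr::write_csv(posterior_draws(fit), path)
  invisible(path)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Hierarchical coverage trend fit (", x$outcome, ", ", x$stratum, ")\n",
      sep = "")
  cat("  countries: ", length(x$countries), ", observations: ", x$n_obs, "\n",
      sep = "")
  cat("  chains: ", x$config$n_chains, " x ", nrow(x$chains[[1]]),
      " retained draws\n", sep = "")
  if (!is.null(x$diagnostics)) {
    cat("  max PSRF (monitored): ",
        round(max(x$diagnostics$psrf_point[x$diagnostics$parameter %in%
                                             x$monitored]), 3), "\n", sep = "")
  }
  invisible(x)
}
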