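#' Dummy-code individual records for the determinants model
#'
#' Encodes the categorical covariates against the reference levels of the
#' odds-ratio table (household head under 30, male head, no education,
#' parity 1, no antenatal visits, no media access, poorest quintile, urban
#' residence), giving 21 non-reference indicator columns in a fixed,
#' documented order.
#'
#' @param records A validated individual-record tibble.
#' @return A list: `x` (n x 21 0/1 matrix), `columns` (its column names),
#'   `reference` (named vector of reference levels), `outcome_insd`,
#'   `outcome_sba`, `country_iso`.
#' @export
#' @examples
#' spec <- generator_spec(n_countries = 2, seed = 5)
#' rec <- generate_individuals(spec, n_per_country = 50)
#' d <- encode_design(rec)
#' dim(d$x)
encode_design <- function(records) {
  records <- validate_individuals(records)
  lv <- individual_levels()
  blocks <- purrr::imap(lv, function(levels, v) {
    f <- factor(records[[v]], levels = levels)
    m <- matrix(0, nrow(records), length(levels) - 1,
                dimnames = list(NULL, paste0(v, ":", levels[-1])))
    for (l in levels[-1]) m[, paste0(v, ":", l)] <- as.numeric(f == l)
    m
  })
  x <- do.call(cbind, unname(blocks))
  list(
    x = x,
    columns = colnames(x),
    reference = vapply(lv, `[`, character(1), 1),
    outcome_insd = as.integer(records$outcome_insd),
    outcome_sba = as.integer(records$outcome_sba),
    country_iso = records$country_iso
  )
}

# report perfectly-separating indicator columns before sampling
.check_separation <- function(x, y) {
  sep <- colnames(x)[vapply(seq_len(ncol(x)), function(j) {
    idx <- x[, j] == 1
    n1 <- sum(idx)
    n1 > 0 && (all(y[idx] == 1) || all(y[idx] == 0))
  }, logical(1))]
  if (length(sep) > 0) {
    abort(paste0("complete separation: level(s) ",
                 paste(sep, collapse = ", "),
                 " perfectly predict the outcome"))
  }
}

#' Fit the random-intercept determinants model
#'
#' Bayesian hierarchical logistic regression of an individual-level
#' delivery outcome on the household and maternal covariates, with a
#' random country intercept: logit P(y = 1) = b0 + x'b + u_i,
#' u_i ~ Normal(0, sigma2_u0). Fixed effects get Normal(0, 10^2) priors;
#' the random-intercept SD gets the configured positive prior
#' (half-Cauchy(0, 2.5) by default). Sampling is adaptive
#' Metropolis-within-Gibbs, seed-deterministic, with convergence
#' diagnostics attached.
#'
#' @param records A validated individual-record tibble covering at least
#'   two countries (unless `random_intercept = FALSE`).
#' @param outcome `"INSD"` or `"SBA"`.
#' @param config An [mcmc_config()]; `prior_scale_fixed` defaults to 10
#'   here if left at the trend model's 100.
#' @param random_intercept Set `FALSE` to drop the country intercepts
#'   (single-country checks against a maximum-likelihood fit).
#' @return An object of class `determinant_fit`.
#' @export
fit_determinants <- function(records, outcome = c("INSD", "SBA"),
                             config = mcmc_config(prior_scale_fixed = 10),
                             random_intercept = TRUE) {
  outcome <- match.arg(outcome)
  design <- encode_design(records)
  y <- if (outcome == "INSD") design$outcome_insd else design$outcome_sba
  if (all(y == y[1])) abort("outcomes are all identical; nothing to model")
  countries <- sort(unique(design$country_iso))
  if (random_intercept && length(countries) < 2) {
    abort("the country hierarchy needs at least 2 countries")
  }
  .check_separation(design$x, y)

  col_rows <- lapply(seq_len(ncol(design$x)),
                     function(j) which(design$x[, j] == 1) - 1L)
  ci <- match(design$country_iso, countries) - 1L

  # ML starting values shared across chains, jittered per chain
  ml <- suppressWarnings(
    stats::glm.fit(cbind(1, design$x), y, family = stats::binomial())
  )
  b_init <- ml$coefficients
  b_init[!is.finite(b_init)] <- 0

  par_names <- c("(Intercept)", design$columns,
                 paste0("u[", countries, "]"), "sigma2_u0")
  chains <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 7919L * (ch - 1L))
    init <- b_init + rnorm(length(b_init), 0, 0.1 * ch)
    res <- .determ_chain_cpp(
      as.integer(y), col_rows, ci, length(countries), init,
      random_intercept,
      config$prior_scale_fixed, .sd_family_code(config$prior_family_sd),
      config$prior_scale_sd,
      config$n_iter, config$burn_in, config$thin
    )
    colnames(res$draws) <- par_names
    chains[[ch]] <- res$draws
    accept[[ch]] <- tibble::tibble(
      parameter = c("(Intercept)", design$columns), chain = ch,
      acceptance = as.numeric(res$accept_fixed)
    )
  }

  monitored <- c("(Intercept)", design$columns,
                 if (random_intercept) "sigma2_u0")
  fit <- structure(list(
    chains = chains, parameters = par_names, monitored = monitored,
    columns = design$columns, reference = design$reference,
    countries = countries, outcome = outcome, config = config,
    random_intercept = random_intercept, n_obs = length(y),
    acceptance = dplyr::bind_rows(accept)
  ), class = "determinant_fit")
  fit$diagnostics <- if (config$n_chains >= 2) psrf_table(fit) else NULL
  fit
}

#' Odds-ratio table of a determinants fit
#'
#' Summarises the posterior of each covariate coefficient as an odds ratio
#' with a 95% credible interval, laid out with one row per category level:
#' reference levels print an odds ratio of 1 with no interval, and the
#' final row reports the random-intercept variance sigma2_u0.
#'
#' @param fit A `determinant_fit`.
#' @param estimate Point estimate: posterior `"median"` (default) or
#'   `"mean"`.
#' @return A tibble with columns `characteristic`, `level`, `reference`,
#'   `or`, `cri_low`, `cri_high`.
#' @export
or_table <- function(fit, estimate = c("median", "mean")) {
  estimate <- match.arg(estimate)
  point <- if (estimate == "median") median else mean
  all_draws <- do.call(rbind, fit$chains)
  lv <- individual_levels()
  rows <- purrr::imap(lv, function(levels, v) {
    purrr::map(levels, function(l) {
      if (l == levels[1]) {
        tibble::tibble(characteristic = v, level = l, reference = TRUE,
                       or = 1, cri_low = NA_real_, cri_high = NA_real_)
      } else {
        d <- exp(all_draws[, paste0(v, ":", l)])
        tibble::tibble(characteristic = v, level = l, reference = FALSE,
                       or = point(d),
                       cri_low = unname(quantile(d, 0.025)),
                       cri_high = unname(quantile(d, 0.975)))
      }
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (fit$random_intercept) {
    d <- all_draws[, "sigma2_u0"]
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      characteristic = "random_intercept", level = "sigma2_u0",
      reference = FALSE, or = point(d),
      cri_low = unname(quantile(d, 0.025)),
      cri_high = unname(quantile(d, 0.975))
    ))
  }
  rows
}

#' Write an odds-ratio table to CSV
#'
#' @param table A tibble from [or_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_or_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @export
print.determinant_fit <- function(x, ...) {
  cat("Random-intercept determinants fit (", x$outcome, ")\n", sep = "")
  cat("  observations: ", x$n_obs, ", countries: ", length(x$countries),
      "\n", sep = "")
  cat("  chains: ", x$config$n_chains, " x ", nrow(x$chains[[1]]),
      " retained draws\n", sep = "")
  invisible(x)
}
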