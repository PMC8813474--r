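#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

.summarise_draws <- function(fit, parameters) {
  all_draws <- do.call(rbind, fit$chains)
  purrr::map(parameters, function(p) {
    d <- all_draws[, p]
    tibble::tibble(parameter = p, mean = mean(d), median = median(d),
                   sd = sd(d),
                   cri_low = unname(quantile(d, 0.025)),
                   cri_high = unname(quantile(d, 0.975)))
  }) |>
    dplyr::bind_rows() |>
    (\(s) if (is.null(fit$diagnostics)) s else
      dplyr::left_join(s, fit$diagnostics[, c("parameter", "psrf_point")],
                       by = "parameter"))()
}

#' Tidy posterior summaries of a trend fit
#'
#' @param x A `trend_fit`.
#' @param ... Unused.
#' @return One row per monitored parameter with posterior mean, median,
#'   SD, 95% credible bounds and the Gelman-Rubin point estimate.
#' @export
tidy.trend_fit <- function(x, ...) .summarise_draws(x, x$monitored)

#' @rdname tidy.trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  psrf <- if (is.null(x$diagnostics)) NA_real_ else
    max(x$diagnostics$psrf_point[x$diagnostics$parameter %in% x$monitored])
  tibble::tibble(
    n_obs = x$n_obs, n_countries = length(x$countries),
    n_chains = x$config$n_chains, n_draws = nrow(x$chains[[1]]),
    outcome = x$outcome, stratum = x$stratum, max_psrf = psrf
  )
}

#' Tidy odds-ratio summaries of a determinants fit
#'
#' @param x A `determinant_fit`.
#' @param ... Passed to [or_table()].
#' @return The odds-ratio table (see [or_table()]).
#' @export
tidy.determinant_fit <- function(x, ...) or_table(x, ...)

#' @rdname tidy.determinant_fit
#' @export
glance.determinant_fit <- function(x, ...) {
  psrf <- if (is.null(x$diagnostics)) NA_real_ else
    max(x$diagnostics$psrf_point[x$diagnostics$parameter %in% x$monitored])
  tibble::tibble(
    n_obs = x$n_obs, n_countries = length(x$countries),
    n_chains = x$config$n_chains, n_draws = nrow(x$chains[[1]]),
    outcome = x$outcome, max_psrf = psrf
  )
}

#' Plot projected coverage trajectories
#'
#' Posterior-mean coverage with the 95% credible ribbon, one panel per
#' country.
#'
#' @param trajectories A tibble from [project_coverage()].
#' @param countries Optional subset of ISO codes.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, countries = NULL) {
  if (!is.null(countries)) {
    trajectories <- dplyr::filter(trajectories,
                                  .data$country_iso %in% countries)
  }
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = .data$year, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cri_low,
                                      ymax = .data$cri_high),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~country_iso) +
    ggplot2::labs(x = "Year", y = "Coverage (%)",
                  title = paste0("Projected ", trajectories$outcome[1],
                                 " coverage (", trajectories$stratum[1], ")")) +
    ggplot2::ylim(0, 100)
}

#' Trace plot of a fitted model
#'
#' @param object A `trend_fit` (chains overlaid per parameter).
#' @param parameters Parameters to show (default: hyper-parameters, or the
#'   first six monitored).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trend_fit <- function(object, parameters = NULL, ...) {
  parameters <- parameters %||%
    intersect(c("mu_alpha", "mu_beta", "sigma_alpha", "sigma_beta",
                "gamma_sdi", "gamma_hrh"), object$monitored)
  if (length(parameters) == 0) parameters <- head(object$monitored, 6)
  ggplot2::ggplot(posterior_draws(object, parameters),
                  ggplot2::aes(x = .data$iteration, y = .data$value,
                               colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "Chain", x = "Retained draw", y = "Value")
}

#' Forest plot of determinant odds ratios
#'
#' @param object A `determinant_fit`.
#' @param ... Passed to [or_table()].
#' @return A ggplot object.
#' @export
autoplot.determinant_fit <- function(object, ...) {
  tab <- or_table(object, ...) |>
    dplyr::filter(.data$characteristic != "random_intercept") |>
    dplyr::mutate(label = paste0(.data$characteristic, ": ", .data$level))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$or,
                                    y = factor(.data$label,
                                               levels = rev(tab$label)))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$cri_low,
                                         xmax = .data$cri_high),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CrI, log scale)", y = NULL,
                  title = paste0("Determinants of ", object$outcome))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
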