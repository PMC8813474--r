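# comparison happens on values as printed, i.e. rounded to one decimal
.printed <- function(x) round(x, 1)

.pred_cells <- function(predictions, year, outcomes) {
  cells <- dplyr::filter(predictions, .data$year == !!year,
                         .data$outcome %in% outcomes)
  countries <- unique(predictions$country_iso)
  expected <- length(countries) * length(outcomes)
  if (nrow(cells) != expected) {
    have <- paste(cells$country_iso, cells$outcome)
    want <- as.vector(outer(countries, outcomes, paste))
    abort(paste0("missing prediction cells for year ", year, ": ",
                 paste(head(setdiff(want, have), 8), collapse = ", ")))
  }
  cells
}

#' Count countries meeting a coverage threshold
#'
#' A country counts as meeting the threshold if its mean predicted
#' coverage, on the values as printed (one decimal), is at or above the
#' threshold for every requested outcome.
#'
#' @param predictions A prediction table ([load_printed_predictions()] or
#'   [project_coverage()] output with a `country_iso` column) containing
#'   the requested year and outcomes for every country.
#' @param year Calendar year to assess.
#' @param outcomes One or both of `"INSD"`, `"SBA"`; with both, a country
#'   must meet the threshold on each.
#' @param threshold Coverage threshold in percent (default 80).
#' @return A one-row tibble of class `threshold_report`: `year`,
#'   `outcomes`, `threshold`, `direction`, `count` and a `countries`
#'   list-column of the qualifying ISO3 codes.
#' @export
#' @examples
#' count_above_threshold(load_printed_predictions(), 2018,
#'                       c("INSD", "SBA"), 80)
count_above_threshold <- function(predictions, year,
                                  outcomes = c("INSD", "SBA"),
                                  threshold = 80) {
  cells <- .pred_cells(predictions, year, outcomes)
  meeting <- cells |>
    dplyr::summarise(ok = all(.printed(.data$mean) >= threshold),
                     .by = "country_iso") |>
    dplyr::filter(.data$ok) |>
    dplyr::pull("country_iso") |>
    sort()
  tibble::new_tibble(list(
    year = as.integer(year), outcomes = list(outcomes),
    threshold = threshold, direction = "above",
    count = length(meeting), countries = list(meeting)
  ), nrow = 1L, class = "threshold_report")
}

#' Count countries below a coverage threshold
#'
#' The complement of [count_above_threshold()] for a single outcome: a
#' country counts when its printed mean coverage is strictly below the
#' threshold.
#'
#' @inheritParams count_above_threshold
#' @param outcome A single outcome.
#' @return A one-row `threshold_report` tibble.
#' @export
#' @examples
#' count_below_threshold(load_printed_predictions(), 2030, "SBA", 80)
count_below_threshold <- function(predictions, year, outcome,
                                  threshold = 80) {
  stopifnot(length(outcome) == 1)
  cells <- .pred_cells(predictions, year, outcome)
  below <- sort(cells$country_iso[.printed(cells$mean) < threshold])
  tibble::new_tibble(list(
    year = as.integer(year), outcomes = list(outcome),
    threshold = threshold, direction = "below",
    count = length(below), countries = list(below)
  ), nrow = 1L, class = "threshold_report")
}

#' Format a "mean (low-high)" table cell
#'
#' @param mean,cri_low,cri_high Values in percent.
#' @return Character cells rounded to one decimal, e.g.
#'   `"94.6 (85.1–98.7)"`.
#' @export
format_cri <- function(mean, cri_low, cri_high) {
  sprintf("%.1f (%.1f–%.1f)", mean, cri_low, cri_high)
}

#' Assemble a country-by-year coverage report
#'
#' Lays out trajectory estimates (or the packaged prediction table) as one
#' row per country and outcome, grouped in the standard six-region order,
#' with `"mean (low-high)"` cells rounded to one decimal for each requested
#' year.
#'
#' @param trajectories A tibble with `country_iso`, `outcome`, `year`,
#'   `mean`, `cri_low`, `cri_high`, and optionally `region` and
#'   `country_name`; must cover every requested year.
#' @param years Report years (default 2000, 2018, 2030).
#' @return A tibble with one row per country-outcome and one formatted
#'   column per year; zero rows in, header-only out.
#' @export
assemble_country_table <- function(trajectories, years = c(2000, 2018, 2030)) {
  if (nrow(trajectories) == 0) {
    return(tibble::tibble(region = character(), country = character(),
                          outcome = character(),
                          !!!setNames(rep(list(character()), length(years)),
                                      paste0("y", years))))
  }
  missing_years <- setdiff(years, trajectories$year)
  if (length(missing_years) > 0) {
    abort(paste0("trajectories lack year(s) ",
                 paste(missing_years, collapse = ", ")))
  }
  out <- trajectories |>
    dplyr::filter(.data$year %in% years) |>
    dplyr::mutate(
      cell = format_cri(.data$mean, .data$cri_low, .data$cri_high),
      region = if ("region" %in% names(trajectories)) .data$region else NA_character_,
      country = if ("country_name" %in% names(trajectories))
        .data$country_name else .data$country_iso
    ) |>
    dplyr::select("region", "country", "outcome", "year", "cell") |>
    tidyr::pivot_wider(names_from = "year", values_from = "cell",
                       names_prefix = "y") |>
    dplyr::arrange(factor(.data$region, levels = lmic_regions()),
                   .data$country, .data$outcome)
  out
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Threshold report: ", x$count, " countries with ",
      paste(x$outcomes[[1]], collapse = " & "), " ",
      if (x$direction == "above") ">=" else "<", " ", x$threshold,
      "% in ", x$year, "\n", sep = "")
  cat("  ", paste(x$countries[[1]], collapse = ", "), "\n", sep = "")
  invisible(x)
}
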