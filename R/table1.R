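.TABLE1_MD5 <- "87b2cb6b7f160586ea69e455475960e2"

#' Published national coverage predictions for the 54 countries
#'
#' Loads the packaged table of published national predicted coverages of
#' institutional delivery (INSD) and skilled birth attendance (SBA) among
#' adolescent mothers in 54 low- and middle-income countries, for the years
#' 2000, 2018 and 2030, each as a posterior mean with a 95% credible
#' interval, all in percent. This fixture is the reference for the
#' threshold-count reports ([count_above_threshold()]).
#'
#' @param check Verify the packaged file's MD5 checksum before loading
#'   (default `TRUE`); a mismatch aborts with a corruption message.
#' @return A tibble with 324 rows (54 countries x 2 outcomes x 3 years) and
#'   columns `country_name`, `country_iso`, `region`, `outcome`, `year`,
#'   `mean`, `cri_low`, `cri_high`.
#' @export
#' @examples
#' preds <- load_printed_predictions()
#' dplyr::n_distinct(preds$country_iso)
load_printed_predictions <- function(check = TRUE) {
  path <- system.file("extdata", "table1_predictions.csv",
                      package = "delivcov", mustWork = TRUE)
  if (check) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .TABLE1_MD5)) {
      abort("packaged prediction table is corrupted (checksum mismatch)")
    }
  }
  preds <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           locale = readr::locale(encoding = "UTF-8"))
  preds$year <- as.integer(preds$year)
  tibble::as_tibble(preds)
}

#' Look up one published prediction cell
#'
#' @param predictions The tibble from [load_printed_predictions()].
#' @param country A country name or ISO3 code.
#' @param outcome `"INSD"` or `"SBA"`.
#' @param year One of 2000, 2018, 2030.
#' @return A one-row tibble; an absent key is an error.
#' @export
#' @examples
#' prediction_cell(load_printed_predictions(), "Afghanistan", "INSD", 2030)
prediction_cell <- function(predictions, country, outcome, year) {
  hit <- dplyr::filter(
    predictions,
    (.data$country_name == country | .data$country_iso == country),
    .data$outcome == !!outcome, .data$year == !!year
  )
  if (nrow(hit) != 1) {
    abort(paste0("no prediction for (", country, ", ", outcome, ", ", year, ")"))
  }
  hit
}
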