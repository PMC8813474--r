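#' Validate a table of survey coverage points
#'
#' A survey point is one observed coverage estimate for a country, survey
#' year, stratum and outcome, together with its design-effect-adjusted
#' (effective) sample size. Validation checks every row against the schema
#' invariants: coverage in \[0, 1\], positive effective sample size,
#' recognised region/stratum/outcome/source labels, and uniqueness of the
#' (country, year, stratum, outcome, source) key.
#'
#' @param points A data frame with columns `country_iso`, `region`,
#'   `survey_year`, `source`, `stratum`, `outcome`, `coverage`,
#'   `n_effective`.
#' @param strict If `TRUE` (default) any invalid row aborts with a message
#'   naming the offending rows; if `FALSE` invalid rows are dropped with a
#'   warning.
#' @return A validated tibble (invisibly the same rows, minus dropped ones
#'   in lenient mode).
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   country_iso = "AFG", region = "South Asia", survey_year = 2010L,
#'   source = "DHS", stratum = "national", outcome = "INSD",
#'   coverage = 0.45, n_effective = 800
#' )
#' validate_survey_points(pts)
validate_survey_points <- function(points, strict = TRUE) {
  points <- tibble::as_tibble(points)
  required <- c("country_iso", "region", "survey_year", "source", "stratum",
                "outcome", "coverage", "n_effective")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0) {
    abort(paste0("survey points are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  problems <- character(0)
  bad <- rep(FALSE, nrow(points))
  flag <- function(cond, what) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) {
      problems <<- c(problems, paste0(what, " (rows ",
                                      paste(which(cond), collapse = ", "), ")"))
      bad <<- bad | cond
    }
  }
  flag(!(points$coverage >= 0 & points$coverage <= 1),
       "coverage outside [0, 1]")
  flag(!(points$n_effective > 0), "n_effective not positive")
  flag(!points$region %in% lmic_regions(), "unknown region")
  flag(!points$stratum %in% coverage_strata(), "unknown stratum")
  flag(!points$outcome %in% coverage_outcomes(), "unknown outcome")
  flag(!points$source %in% c("DHS", "MICS", "SYNTH"), "unknown source")
  key <- paste(points$country_iso, points$survey_year, points$stratum,
               points$outcome, points$source)
  flag(duplicated(key), "duplicate (country, year, stratum, outcome, source) key")
  if (length(problems) > 0) {
    msg <- paste0("invalid survey points: ", paste(problems, collapse = "; "))
    if (strict) abort(msg)
    warn(paste0(msg, " - dropped in lenient mode"))
    points <- points[!bad, , drop = FALSE]
  }
  points
}

#' Read and write survey coverage points
#'
#' CSV round-trip for the survey-point schema. Reading validates every row;
#' in strict mode a malformed row aborts with its row number, in lenient
#' mode it is skipped with a warning.
#'
#' @param path Path to a CSV file with the survey-point columns.
#' @param strict Passed to [validate_survey_points()].
#' @return `read_survey_points()` returns a validated tibble;
#'   `write_survey_points()` returns `path` invisibly.
#' @export
read_survey_points <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  pts <- validate_survey_points(raw, strict = strict)
  pts$survey_year <- as.integer(pts$survey_year)
  pts
}

#' @rdname read_survey_points
#' @param points A survey-point tibble.
#' @export
write_survey_points <- function(points, path) {
  readr::write_csv(validate_survey_points(points), path)
  invisible(path)
}

#' Effective sample size from a raw survey denominator
#'
#' Cluster surveys inflate sampling variance relative to simple random
#' sampling; dividing the raw denominator by the design effect gives the
#' effective sample size used as the binomial denominator.
#'
#' @param raw_n Raw number of respondents (positive).
#' @param design_effect Variance inflation factor; defaults to 2, a typical
#'   value for multi-stage cluster household surveys.
#' @return `raw_n / design_effect`.
#' @export
#' @examples
#' effective_sample_size(2000)
effective_sample_size <- function(raw_n, design_effect = 2) {
  stopifnot(all(raw_n > 0), all(design_effect >= 1))
  raw_n / design_effect
}

#' Validate, read and write country-year covariate series
#'
#' The trend model uses two country-level covariates: the Sociodemographic
#' Index (SDI, in \[0, 1\]) and the Human Resources for Health density (HRH,
#' health workers per 1,000 population, non-negative). A series has one row
#' per country-year.
#'
#' @param covariates A data frame with columns `country_iso`, `year`, `sdi`,
#'   `hrh`.
#' @return A validated tibble.
#' @export
#' @examples
#' cov <- tidyr::expand_grid(country_iso = "NPL", year = 2000:2030)
#' cov$sdi <- 0.4 + 0.005 * (cov$year - 2000)
#' cov$hrh <- 1 + 0.05 * (cov$year - 2000)
#' validate_covariates(cov)
validate_covariates <- function(covariates) {
  covariates <- tibble::as_tibble(covariates)
  required <- c("country_iso", "year", "sdi", "hrh")
  missing_cols <- setdiff(required, names(covariates))
  if (length(missing_cols) > 0) {
    abort(paste0("covariates are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_sdi <- which(!(covariates$sdi >= 0 & covariates$sdi <= 1))
  if (length(bad_sdi) > 0) {
    abort(paste0("sdi outside [0, 1] (rows ", paste(bad_sdi, collapse = ", "), ")"))
  }
  bad_hrh <- which(covariates$hrh < 0)
  if (length(bad_hrh) > 0) {
    abort(paste0("negative hrh (rows ", paste(bad_hrh, collapse = ", "), ")"))
  }
  key <- paste(covariates$country_iso, covariates$year)
  if (anyDuplicated(key)) {
    abort(paste0("duplicate country-year rows: ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  covariates$year <- as.integer(covariates$year)
  covariates
}

#' @rdname validate_covariates
#' @param path Path to a CSV file.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  validate_covariates(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname validate_covariates
#' @export
write_covariates <- function(covariates, path) {
  readr::write_csv(validate_covariates(covariates), path)
  invisible(path)
}

#' Report missing country-years in a covariate series
#'
#' @param covariates A validated covariate tibble.
#' @param years Year range that must be covered for every country present.
#' @return A tibble of (`country_iso`, `year`) pairs absent from the series;
#'   zero rows when there are no gaps.
#' @export
covariate_gaps <- function(covariates, years = 2000:2030) {
  covariates <- validate_covariates(covariates)
  tidyr::expand_grid(country_iso = unique(covariates$country_iso),
                     year = as.integer(years)) |>
    dplyr::anti_join(covariates, by = c("country_iso", "year"))
}

# ---- individual-level records ------------------------------------------

#' Category levels of the individual-record schema
#'
#' The determinants model uses the recode-style categories below; the first
#' level of each is the reference category of the odds-ratio table.
#'
#' @return A named list of character vectors of levels.
#' @export
#' @examples
#' individual_levels()$education
individual_levels <- function() {
  list(
    hh_head_age = c("<30", "30-45", "46-60", ">60"),
    hh_head_sex = c("male", "female"),
    education = c("none", "primary", "secondary", "higher"),
    parity = c("1", "2", "3", ">=4"),
    anc_visits = c("0", "1", "2", "3", ">=4"),
    media = c("none", "<weekly", ">=weekly"),
    wealth_quintile = c("Q1", "Q2", "Q3", "Q4", "Q5"),
    residence = c("urban", "rural")
  )
}

#' Validate, read and write individual-level delivery records
#'
#' One row per most-recent birth of an adolescent mother, with binary
#' institutional-delivery and skilled-attendance outcomes and the household
#' and maternal covariates of the determinants model.
#'
#' @param records A data frame with columns `country_iso`, `outcome_insd`,
#'   `outcome_sba` and the covariates listed by [individual_levels()].
#' @return A validated tibble.
#' @export
validate_individuals <- function(records) {
  records <- tibble::as_tibble(records)
  lv <- individual_levels()
  required <- c("country_iso", "outcome_insd", "outcome_sba", names(lv))
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("individual records are missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (oc in c("outcome_insd", "outcome_sba")) {
    if (!all(records[[oc]] %in% c(0L, 1L))) {
      abort(paste0(oc, " must be 0/1"))
    }
  }
  for (v in names(lv)) {
    bad <- which(!records[[v]] %in% lv[[v]])
    if (length(bad) > 0) {
      abort(paste0("invalid ", v, " value (rows ",
                   paste(head(bad, 5), collapse = ", "),
                   if (length(bad) > 5) ", ..." else "", ")"))
    }
  }
  records
}

#' @rdname validate_individuals
#' @param path Path to a CSV file.
#' @export
read_individuals <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(outcome_insd = "i", outcome_sba = "i",
                            .default = "c")
  )
  validate_individuals(raw)
}

#' @rdname validate_individuals
#' @export
write_individuals <- function(records, path) {
  readr::write_csv(validate_individuals(records), path)
  invisible(path)
}
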