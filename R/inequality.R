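#' Ridit scores of ordered population groups
#'
#' The ridit score of group j is the cumulative population share below the
#' group plus half the group's own share: the midpoint of its interval on
#' the cumulative rank scale.
#'
#' @param shares Population shares of the ordered groups (poorest first),
#'   summing to 1.
#' @return Ridit scores in (0, 1).
#' @export
#' @examples
#' ridit_scores(rep(0.2, 5))
ridit_scores <- function(shares) {
  if (abs(sum(shares) - 1) > 1e-6) abort("group shares must sum to 1")
  if (any(shares <= 0)) abort("group shares must be positive")
  cumsum(shares) - shares / 2
}

#' Slope index of inequality across wealth quintiles
#'
#' The SII is the slope of a weighted least-squares regression of subgroup
#' coverage on ridit scores, with the population shares as weights: the
#' fitted coverage difference between the very top (rank 1) and the very
#' bottom (rank 0) of the cumulative wealth distribution, in percentage
#' points. Positive values indicate pro-rich inequality.
#'
#' @param coverage Coverage (percent) for the five quintiles, Q1 (poorest)
#'   first.
#' @param shares Population shares of the quintiles (default equal fifths).
#' @return A one-row tibble: `sii` (percentage points) and `direction`
#'   (`"pro-rich"`, `"pro-poor"` or `"none"`).
#' @export
#' @examples
#' sii(c(10, 20, 30, 40, 50))
sii <- function(coverage, shares = rep(0.2, 5)) {
  if (length(coverage) != 5 || anyNA(coverage)) {
    abort("five quintile coverages are required (Q1..Q5)")
  }
  if (length(shares) != 5) abort("five quintile shares are required")
  x <- ridit_scores(shares)
  xbar <- sum(shares * x)
  ybar <- sum(shares * coverage)
  slope <- sum(shares * (x - xbar) * (coverage - ybar)) /
    sum(shares * (x - xbar)^2)
  tibble::tibble(
    sii = slope,
    direction = dplyr::case_when(slope > 0 ~ "pro-rich",
                                 slope < 0 ~ "pro-poor",
                                 TRUE ~ "none")
  )
}

#' SII for a table of per-quintile coverages
#'
#' @param quintile_coverage A tibble with columns `country_iso`, `outcome`,
#'   `year` and `Q1`..`Q5` (coverage, percent), plus optional share columns
#'   `share_Q1`..`share_Q5`.
#' @return The input keys with `sii` and `direction` columns appended.
#' @export
sii_table <- function(quintile_coverage) {
  qcols <- paste0("Q", 1:5)
  missing_cols <- setdiff(c("country_iso", "outcome", "year", qcols),
                          names(quintile_coverage))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  scols <- paste0("share_", qcols)
  has_shares <- all(scols %in% names(quintile_coverage))
  quintile_coverage |>
    dplyr::mutate(purrr::pmap_dfr(
      dplyr::pick(dplyr::all_of(c(qcols, if (has_shares) scols))),
      function(...) {
        v <- c(...)
        sii(v[1:5], if (has_shares) v[6:10] else rep(0.2, 5))
      }
    ))
}

#' Posterior SII draws from per-quintile coverage draws
#'
#' The per-draw variant of [sii()]: applies the ridit regression to each
#' posterior draw of the five quintile coverages, giving a credible
#' interval for the SII itself.
#'
#' @param quintile_draws A draws x 5 matrix of quintile coverages
#'   (percent), columns Q1..Q5.
#' @param shares Quintile population shares.
#' @return A one-row tibble: posterior mean `sii`, `cri_low`, `cri_high`
#'   and the `direction` of the posterior mean.
#' @export
sii_draws <- function(quintile_draws, shares = rep(0.2, 5)) {
  stopifnot(is.matrix(quintile_draws), ncol(quintile_draws) == 5)
  x <- ridit_scores(shares)
  xbar <- sum(shares * x)
  w <- shares * (x - xbar)
  slopes <- as.vector(quintile_draws %*% w) / sum(w * (x - xbar))
  m <- mean(slopes)
  tibble::tibble(
    sii = m,
    cri_low = unname(quantile(slopes, 0.025)),
    cri_high = unname(quantile(slopes, 0.975)),
    direction = dplyr::case_when(m > 0 ~ "pro-rich", m < 0 ~ "pro-poor",
                                 TRUE ~ "none")
  )
}

#' Percentage change between two coverage values
#'
#' @param v_start,v_end Coverage in percent, in \[0, 100\].
#' @param mode `"point"` (default): the difference in percentage points,
#'   `v_end - v_start`; `"relative"`: the change as a percentage of the
#'   starting value, `100 (v_end - v_start) / v_start`.
#' @return A numeric vector of changes.
#' @export
#' @examples
#' percentage_change(4.7, 94.6)           # point change
#' percentage_change(40, 60, "relative")  # relative change
percentage_change <- function(v_start, v_end, mode = c("point", "relative")) {
  mode <- match.arg(mode)
  stopifnot(all(v_start >= 0 & v_start <= 100),
            all(v_end >= 0 & v_end <= 100))
  if (mode == "point") return(v_end - v_start)
  if (any(v_start == 0)) abort("relative change is undefined for v_start = 0")
  100 * (v_end - v_start) / v_start
}

#' Urban-rural coverage gap
#'
#' @param urban,rural Coverage in percent.
#' @param wide_threshold Gaps at or above this many percentage points are
#'   classified as wide (default 30).
#' @return A tibble with columns `gap` (urban minus rural, percentage
#'   points) and `wide`.
#' @export
#' @examples
#' residence_gap(90, 55)
residence_gap <- function(urban, rural, wide_threshold = 30) {
  stopifnot(all(urban >= 0 & urban <= 100), all(rural >= 0 & rural <= 100))
  gap <- urban - rural
  tibble::tibble(gap = gap, wide = gap >= wide_threshold)
}
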