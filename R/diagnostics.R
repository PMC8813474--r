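#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split, non-rank-normalised) PSRF for one scalar parameter
#' monitored across parallel chains. With m chains of length n, W is the
#' mean within-chain variance, B/n the variance of the chain means, and the
#' pooled variance estimate is V = ((n-1)/n) W + B/n. The point estimate is
#' sqrt(V/W); the upper limit replaces the between-chain term by its 97.5th
#' percentile under an F(m-1, m(n-1)) approximation to the between/within
#' variance ratio. Chains whose upper limit exceeds `flag_threshold` are
#' flagged for attention.
#'
#' @param chains A list of (at least two) equal-length numeric vectors, or
#'   a matrix with one chain per column.
#' @param split Split each chain in half first (a stricter variant that
#'   also detects within-chain drift); off by default, matching the classic
#'   estimator.
#' @param flag_threshold Flagging threshold on the upper limit (default 1.1,
#'   the common rule of thumb).
#' @param parameter Parameter name recorded in the report.
#' @return A one-row tibble: `parameter`, `psrf_point`, `psrf_upper`,
#'   `flag`.
#' @export
#' @examples
#' gelman_rubin(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
gelman_rubin <- function(chains, split = FALSE, flag_threshold = 1.1,
                         parameter = "parameter") {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), \(j) chains[, j])
  if (length(chains) < 2) abort("at least two chains are required")
  n1 <- unique(lengths(chains))
  if (length(n1) != 1) abort("chains must have equal length")
  if (split) {
    half <- n1 %/% 2
    chains <- unlist(lapply(chains, function(ch) {
      list(ch[seq_len(half)], ch[seq(length(ch) - half + 1, length(ch))])
    }), recursive = FALSE)
  }
  m <- length(chains)
  n <- lengths(chains)[1]
  if (n < 4) abort("chains must have length at least 4")
  W <- mean(vapply(chains, var, numeric(1)))
  if (W == 0) abort("degenerate chains: within-chain variance is zero")
  B_over_n <- var(vapply(chains, mean, numeric(1)))
  psrf_point <- sqrt((n - 1) / n + B_over_n / W)
  psrf_upper <- sqrt((n - 1) / n +
                       qf(0.975, m - 1, m * (n - 1)) * B_over_n / W)
  tibble::tibble(parameter = parameter,
                 psrf_point = psrf_point, psrf_upper = psrf_upper,
                 flag = psrf_upper > flag_threshold)
}

#' Convergence report for every monitored parameter of a fit
#'
#' @param fit A `trend_fit` or `determinant_fit`.
#' @param parameters Parameters to assess; defaults to the fit's monitored
#'   set. Parameters held constant across all chains (fixed by the
#'   configuration) are skipped.
#' @param ... Passed to [gelman_rubin()].
#' @return A tibble with one row per parameter.
#' @export
psrf_table <- function(fit, parameters = NULL, ...) {
  parameters <- parameters %||% fit$monitored
  purrr::map(parameters, function(p) {
    ch <- lapply(fit$chains, \(m) m[, p])
    if (all(vapply(ch, var, numeric(1)) == 0)) return(NULL)
    gelman_rubin(ch, parameter = p, ...)
  }) |>
    dplyr::bind_rows()
}

#' Write a diagnostics table to CSV
#'
#' @param diagnostics A tibble from [psrf_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(diagnostics, path) {
  readr::write_csv(diagnostics, path)
  invisible(path)
}

#' Running-mean trace summaries
#'
#' A numerical companion to visual trace inspection: the running mean of
#' each chain, which should converge to the pooled mean for a stationary,
#' well-mixed sampler.
#'
#' @param chains A list of numeric vectors or a one-chain numeric vector.
#' @return A tibble with columns `chain`, `iteration`, `value`,
#'   `running_mean`; the pooled mean across chains is attached as the
#'   `pooled_mean` attribute.
#' @export
#' @examples
#' trace_summary(list(c(0, 1, 0, 1), c(1, 0, 1, 0)))
trace_summary <- function(chains) {
  if (is.numeric(chains)) chains <- list(chains)
  if (length(chains) == 0 || any(lengths(chains) == 0)) {
    abort("chains must be non-empty")
  }
  out <- purrr::imap(chains, function(ch, i) {
    tibble::tibble(chain = as.integer(i), iteration = seq_along(ch),
                   value = ch, running_mean = cumsum(ch) / seq_along(ch))
  }) |>
    dplyr::bind_rows()
  attr(out, "pooled_mean") <- mean(unlist(chains))
  out
}

#' Acceptance rates of a fitted model's proposal blocks
#'
#' @param fit A `trend_fit` or `determinant_fit`.
#' @return A tibble with columns `parameter`, `chain`, `acceptance`, all
#'   rates in \[0, 1\].
#' @export
acceptance_rates <- function(fit) fit$acceptance
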