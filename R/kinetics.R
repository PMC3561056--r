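#' Initial reaction rate from a kinetic trace
#'
#' Ordinary least-squares slope of fluorescence versus time over the first
#' `window_fraction` of the trace span.  The full ~10 minute read is the
#' default window; restrict the fraction for strongly curved traces where the
#' linear fit underestimates the t -> 0 tangent.
#'
#' @param trace data frame with columns `time_min` and `rfu` (a single
#'   compound x concentration trace), or a list/tibble with numeric `times`
#'   and `rfu` elements.
#' @param window_fraction fraction of the time span to fit, in (0, 1\].
#' @return one-row tibble: `slope` (RFU/min), `intercept` (RFU),
#'   `r_squared`, `t_start`, `t_end`, `n_points`.
#' @examples
#' initial_rate(tibble::tibble(time_min = 0:2, rfu = c(0, 10, 20)))
#' @export
initial_rate <- function(trace, window_fraction = 1.0) {
  check_that(window_fraction > 0 && window_fraction <= 1,
             "window_fraction must be in (0, 1]")
  times <- if (!is.null(trace$time_min)) trace$time_min else trace$times
  rfu <- trace$rfu
  check_that(!is.null(times) && !is.null(rfu) && length(times) == length(rfu),
             "trace needs matching time and rfu vectors")
  t_end <- min(times) + window_fraction * diff(range(times))
  keep <- times <= t_end + sqrt(.Machine$double.eps)
  times <- times[keep]
  rfu <- rfu[keep]
  check_that(length(times) >= 3, "need at least 3 points in the fit window")
  check_that(sd(times) > 0, "zero time variance in the fit window")
  fit <- lm(rfu ~ times)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((rfu - mean(rfu))^2)
  tibble(slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         t_start = min(times),
         t_end = max(times),
         n_points = length(times))
}

#' Initial rates for every compound x concentration trace of a screen
#'
#' Applies [initial_rate()] to each group of a long trace table.
#'
#' @param traces long tibble `compound`, `conc_M`, `time_min`, `rfu` (the
#'   [simulate_kinetic_screen()] dialect).
#' @param window_fraction forwarded to [initial_rate()].
#' @return tibble with one row per compound x concentration and the
#'   [initial_rate()] columns.
#' @export
screen_rates <- function(traces, window_fraction = 1.0) {
  traces <- as_tibble(traces)
  check_that(all(c("compound", "conc_M", "time_min", "rfu") %in% names(traces)),
             "traces needs columns compound, conc_M, time_min, rfu")
  out <- dplyr::reframe(
    dplyr::group_by(traces, .data$compound, .data$conc_M),
    initial_rate(dplyr::pick(dplyr::everything()), window_fraction)
  )
  dplyr::ungroup(out)
}

#' Percent inhibition relative to the vehicle rate
#'
#' `100 * (1 - slope / vehicle_slope)`: 0% for an uninhibited trace, 100% for
#' a fully suppressed one.  Values are capped above at 100 (a slightly
#' negative fitted slope cannot exceed full inhibition) but activation below
#' 0% is reported as negative inhibition, unclamped.
#'
#' @param slope compound initial rate(s), RFU/min (or a one-row rate tibble).
#' @param vehicle_slope vehicle (no-compound) rate, RFU/min; must be > 0.
#' @return percent inhibition, same length as `slope`.
#' @export
percent_inhibition <- function(slope, vehicle_slope) {
  if (is.data.frame(slope)) slope <- slope$slope
  if (is.data.frame(vehicle_slope)) vehicle_slope <- vehicle_slope$slope
  check_that(length(vehicle_slope) == 1 && is.finite(vehicle_slope) &&
               vehicle_slope > 0, "degenerate vehicle: slope must be > 0")
  pmin(100, 100 * (1 - slope / vehicle_slope))
}
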