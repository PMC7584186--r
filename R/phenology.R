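# Bloom phenology: Gaussian opening-rate curves integrated in closed form.
# The opening rate of a sex with B buds, peak day mu and spread s is
# B * dnorm((t - mu)/s)/s, so the cumulative number opened by time t (with
# nothing open before t = 0) is B * (pnorm((t - mu)/s) - pnorm(-mu/s)).

#' Cumulative number of flowers opened by time t
#'
#' Integral from day 0 of the Gaussian opening-rate curve. Nothing is open
#' before time 0, so a small fraction of buds (the Gaussian mass that falls
#' before day 0) never opens.
#'
#' @param t Time in days (vectorised). Times `<= 0` return 0.
#' @param buds Total bud count for the sex.
#' @param peak Day of peak opening rate.
#' @param spread Spread (standard deviation) of the opening curve, days.
#' @return Cumulative flowers opened, nondecreasing in `t`, bounded by
#'   `buds`.
#' @examples
#' cumulative_opened(6, buds = 600000, peak = 6, spread = 2.5)
#' @export
cumulative_opened <- function(t, buds, peak, spread) {
  check_phenology_args(buds, peak, spread)
  if (any(!is.finite(t) & !is.infinite(t)))
    stop("cumulative_opened: t must not contain NA/NaN", call. = FALSE)
  out <- buds * (pnorm((t - peak) / spread) - pnorm(-peak / spread))
  out[t <= 0] <- 0
  pmax(out, 0)
}

check_phenology_args <- function(buds, peak, spread) {
  if (!is.finite(buds) || buds < 0)
    stop("phenology: buds must be finite and >= 0", call. = FALSE)
  if (!is.finite(peak) || peak < 0)
    stop("phenology: peak must be finite and >= 0", call. = FALSE)
  if (!is.finite(spread) || spread <= 0)
    stop("phenology: spread must be finite and > 0", call. = FALSE)
  invisible(NULL)
}

#' Number of flowers currently open at time t
#'
#' Flowers open for a fixed lifespan and then close, so the open count is the
#' difference of the cumulative-opened curve at `t` and at `t - lifespan`.
#'
#' @inheritParams cumulative_opened
#' @param lifespan Days an individual flower stays open.
#' @return Open-flower count in `[0, buds]`.
#' @export
open_count <- function(t, buds, peak, spread, lifespan) {
  if (!is.finite(lifespan) && !is.infinite(lifespan))
    stop("open_count: lifespan must not be NA/NaN", call. = FALSE)
  if (lifespan <= 0)
    stop("open_count: lifespan must be > 0", call. = FALSE)
  if (is.infinite(lifespan))
    return(cumulative_opened(t, buds, peak, spread))
  cumulative_opened(t, buds, peak, spread) -
    cumulative_opened(t - lifespan, buds, peak, spread)
}

#' Daily number of female flowers closing
#'
#' Number of female flowers closing during the day-long window
#' `[day, day + 1)`: the flowers that opened during
#' `[day - lifespan, day + 1 - lifespan)`.
#'
#' @param day Integer day index (vectorised), `>= 0`.
#' @param flowers A [flower_params()] object.
#' @return Expected count of female flowers closing that day.
#' @export
daily_female_closing <- function(day, flowers) {
  stopifnot(inherits(flowers, "flower_params"))
  if (any(!is.finite(day)) || any(day < 0))
    stop("daily_female_closing: day must be finite and >= 0", call. = FALSE)
  tau <- flowers$lifespan_female
  cumulative_opened(day + 1 - tau, flowers$buds_female,
                    flowers$peak_female, flowers$spread_female) -
    cumulative_opened(day - tau, flowers$buds_female,
                      flowers$peak_female, flowers$spread_female)
}

#' Open-flower trajectories for both sexes
#'
#' Evaluates cumulative and currently-open flower counts for both sexes on a
#' uniform time grid, plus the daily female closing counts.
#'
#' @param flowers A [flower_params()] object.
#' @param horizon End of the time grid (days); default from the scenario
#'   horizon rule.
#' @param grid_step Grid spacing (days).
#' @return A data frame of class `bloom_trajectory` with columns `time`,
#'   `m`, `f` (open counts), `M`, `F` (cumulative counts), and an attribute
#'   `daily_female_closing` (named vector over integer days).
#' @export
bloom_trajectory <- function(flowers, horizon = NULL, grid_step = 0.01) {
  stopifnot(inherits(flowers, "flower_params"))
  if (is.null(horizon)) horizon <- default_horizon(flowers)
  if (grid_step <= 0) stop("bloom_trajectory: grid_step must be > 0",
                           call. = FALSE)
  times <- seq(0, horizon, by = grid_step)
  out <- data.frame(
    time = times,
    m = open_count(times, flowers$buds_male, flowers$peak_male,
                   flowers$spread_male, flowers$lifespan_male),
    f = open_count(times, flowers$buds_female, flowers$peak_female,
                   flowers$spread_female, flowers$lifespan_female),
    M = cumulative_opened(times, flowers$buds_male, flowers$peak_male,
                          flowers$spread_male),
    F = cumulative_opened(times, flowers$buds_female, flowers$peak_female,
                          flowers$spread_female)
  )
  days <- seq_len(max(floor(horizon), 1L)) - 1L
  dfc <- daily_female_closing(days, flowers)
  attr(out, "daily_female_closing") <- setNames(dfc, days)
  class(out) <- c("bloom_trajectory", "data.frame")
  out
}

#' Overlap of male and female bloom
#'
#' Diagnostic for how much of the bloom both sexes are open simultaneously:
#' the pointwise minimum of the two open-flower curves and its integral over
#' the horizon (trapezoid rule, flower-days).
#'
#' @inheritParams bloom_trajectory
#' @return List with `time`, `overlap` (min of the open counts) and
#'   `integral` (flower-days).
#' @export
bloom_overlap <- function(flowers, horizon = NULL, grid_step = 0.01) {
  traj <- bloom_trajectory(flowers, horizon = horizon, grid_step = grid_step)
  ov <- pmin(traj$m, traj$f)
  n <- length(ov)
  integral <- sum((ov[-1] + ov[-n]) / 2 * diff(traj$time))
  list(time = traj$time, overlap = ov, integral = integral)
}
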