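#' Flower (bloom phenology) parameters
#'
#' Bundle the parameters governing when male and female flowers open and how
#' long they stay open. Opening rates follow Gaussian curves: the male rate
#' peaks on day `peak_male` with spread `spread_male`, and integrates (from
#' day 0) to at most `buds_male` flowers; likewise for females. Every flower
#' stays open for a fixed, sex-specific lifespan and then closes.
#'
#' @param buds_male,buds_female Total number of male / female flower buds in
#'   the modelled orchard block (flowers; the defaults describe 1 ha).
#' @param peak_male,peak_female Day of peak opening rate (days from the start
#'   of bloom).
#' @param spread_male,spread_female Standard deviation of the opening-rate
#'   curve (days); must be positive.
#' @param lifespan_male,lifespan_female Number of days an individual flower
#'   remains open (days); must be positive.
#'
#' @return An object of class `flower_params`.
#' @examples
#' fp <- flower_params()
#' fp$buds_female
#' @export
flower_params <- function(buds_male = 600000, buds_female = 600000,
                          peak_male = 6, peak_female = 6,
                          spread_male = 2.5, spread_female = 2,
                          lifespan_male = 4, lifespan_female = 5) {
  p <- list(
    buds_male = buds_male, buds_female = buds_female,
    peak_male = peak_male, peak_female = peak_female,
    spread_male = spread_male, spread_female = spread_female,
    lifespan_male = lifespan_male, lifespan_female = lifespan_female
  )
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("flower_params: `", nm, "` must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$buds_male < 0 || p$buds_female < 0)
    stop("flower_params: bud counts must be >= 0", call. = FALSE)
  if (p$peak_male < 0 || p$peak_female < 0)
    stop("flower_params: peak days must be >= 0", call. = FALSE)
  if (p$spread_male <= 0 || p$spread_female <= 0)
    stop("flower_params: spreads must be > 0", call. = FALSE)
  if (p$lifespan_male <= 0 || p$lifespan_female <= 0)
    stop("flower_params: lifespans must be > 0", call. = FALSE)
  structure(p, class = "flower_params")
}

#' Pollinator behaviour parameters
#'
#' Parameters of the pollinator visitation and movement model. The total
#' per-pollinator visitation rate is a Holling type II function of the number
#' of open flowers, `alpha * x / (1 + alpha * beta * x)`, saturating at
#' `1/beta` visits per day. Movement between flower sexes is governed by the
#' preference exponents: a pollinator currently on a male flower stays on
#' male flowers with probability `(m/(m+f))^pref_male`, and symmetrically for
#' females. Exponent 1 means no preference (movement follows flower shares);
#' exponents near 0 mean a strong tendency to remain on the current sex.
#'
#' @param search_rate Encounter-rate coefficient `alpha`
#'   (1/(day x flower)). The default 480 corresponds to encountering 2
#'   flowers per minute over a 4-hour active foraging day.
#' @param handling_time Time spent per flower visit, `beta`, in (active)
#'   days; caps the visitation rate at `1/handling_time`. Default 0.0011
#'   days (16 s of the 4-hour foraging window). See
#'   [handling_seconds_to_days()].
#' @param pref_male,pref_female Preference exponents `delta` (remain on male
#'   flowers) and `epsilon` (remain on female flowers), in `[0, 1]`. Defaults
#'   are calibrated so that with equal open flowers the stay probabilities are
#'   0.957 (male) and 0.951 (female); see [preference_from_stay()].
#' @param density Pollinators per 1000 female buds, `rho`. How the absolute
#'   pollinator count is derived is set by the scenario's `rho_basis`.
#'
#' @return An object of class `pollinator_params`.
#' @export
pollinator_params <- function(search_rate = 480, handling_time = 0.0011,
                              pref_male = preference_from_stay(0.957),
                              pref_female = preference_from_stay(0.951),
                              density = 6) {
  p <- list(search_rate = search_rate, handling_time = handling_time,
            pref_male = pref_male, pref_female = pref_female,
            density = density)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("pollinator_params: `", nm, "` must be a single finite number",
           call. = FALSE)
    }
  }
  if (p$search_rate <= 0)
    stop("pollinator_params: search_rate must be > 0", call. = FALSE)
  if (p$handling_time < 0)
    stop("pollinator_params: handling_time must be >= 0", call. = FALSE)
  if (p$pref_male < 0 || p$pref_male > 1 ||
      p$pref_female < 0 || p$pref_female > 1)
    stop("pollinator_params: preference exponents must lie in [0, 1]",
         call. = FALSE)
  if (p$density < 0)
    stop("pollinator_params: density must be >= 0", call. = FALSE)
  structure(p, class = "pollinator_params")
}

#' Per-visit fruit-set probabilities
#'
#' Chance that a single pollen-depositing visit fully pollinates a female
#' flower, by visit type. A type-one visit is made by a high-load pollinator,
#' type two by a medium-load one, type three by a low-load one; each visit
#' type deposits progressively less pollen.
#'
#' @param p1,p2,p3 Probabilities in `[0, 1]` for type one, two and three
#'   visits respectively.
#' @return An object of class `fruitset_params`.
#' @export
fruitset_params <- function(p1 = 0.66, p2 = 0.55, p3 = 0.22) {
  p <- list(p1 = p1, p2 = p2, p3 = p3)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("fruitset_params: `", nm, "` must be a probability in [0, 1]",
           call. = FALSE)
  }
  structure(p, class = "fruitset_params")
}

#' Assemble a simulation scenario
#'
#' A scenario bundles flower, pollinator and fruit-set parameters with the
#' numerical controls of the integration. The default horizon rule,
#' `max(peaks) + 4 * max(spreads) + max(lifespans) + 1` days, guarantees that
#' more than 99.99% of the opening mass has both opened and closed by the end
#' of the run.
#'
#' @param flowers A [flower_params()] object.
#' @param pollinators A [pollinator_params()] object.
#' @param fruitset A [fruitset_params()] object.
#' @param horizon Simulation end time in days, or `NULL` for the default
#'   horizon rule.
#' @param grid_step Output grid spacing in days (default 0.01).
#' @param rtol,atol Relative / absolute solver tolerances.
#' @param rho_basis Either `"per_female"` (pollinator count =
#'   `density * buds_female / 1000`, the default) or `"per_all"`
#'   (`density * (buds_male + buds_female) / 1000`).
#' @param close_time How a closing day's visit exposure is aggregated:
#'   `"weighted"` (default; exposures averaged over the day weighted by the
#'   closing density, which balances the visits-delivered/visits-received
#'   books exactly), `"midpoint"` or `"end"` (single-time evaluation).
#' @param accrual_guard Open-female-flower count below which per-flower visit
#'   accrual is set to 0, guarding the 0/0 at the bloom edges.
#'
#' @return An object of class `scenario`.
#' @examples
#' sc <- scenario()
#' n_pollinators(sc)
#' @export
scenario <- function(flowers = flower_params(),
                     pollinators = pollinator_params(),
                     fruitset = fruitset_params(),
                     horizon = NULL, grid_step = 0.01,
                     rtol = 1e-8, atol = 1e-6,
                     rho_basis = c("per_female", "per_all"),
                     close_time = c("weighted", "midpoint", "end"),
                     accrual_guard = 1e-6) {
  stopifnot(inherits(flowers, "flower_params"),
            inherits(pollinators, "pollinator_params"),
            inherits(fruitset, "fruitset_params"))
  rho_basis <- match.arg(rho_basis)
  close_time <- match.arg(close_time)
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0)
    stop("scenario: grid_step must be a single positive number", call. = FALSE)
  default_h <- default_horizon(flowers)
  if (is.null(horizon)) {
    horizon <- default_h
  } else {
    if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon))
      stop("scenario: horizon must be a single finite number", call. = FALSE)
    min_h <- max(flowers$peak_male, flowers$peak_female) +
      max(flowers$lifespan_male, flowers$lifespan_female)
    if (horizon <= min_h)
      stop("scenario: horizon must exceed max(peak) + max(lifespan) = ",
           signif(min_h, 4), " days", call. = FALSE)
  }
  structure(list(flowers = flowers, pollinators = pollinators,
                 fruitset = fruitset, horizon = horizon,
                 grid_step = grid_step, rtol = rtol, atol = atol,
                 rho_basis = rho_basis, close_time = close_time,
                 accrual_guard = accrual_guard),
            class = "scenario")
}

default_horizon <- function(flowers) {
  max(flowers$peak_male, flowers$peak_female) +
    4 * max(flowers$spread_male, flowers$spread_female) +
    max(flowers$lifespan_male, flowers$lifespan_female) + 1
}

#' Total pollinator count implied by a scenario
#'
#' @param sc A [scenario()].
#' @return Number of pollinators present throughout the simulation (the
#'   population is closed; all start carrying no pollen).
#' @export
n_pollinators <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  b <- switch(sc$rho_basis,
              per_female = sc$flowers$buds_female,
              per_all = sc$flowers$buds_male + sc$flowers$buds_female)
  sc$pollinators$density * b / 1000
}

#' Convert a handling time in seconds to model days
#'
#' Visitation-rate parameters are expressed per 4-hour active foraging day
#' (14400 s), so a 16 s handling time is 0.0011 model days.
#'
#' @param seconds Handling time in seconds (vectorised).
#' @return Handling time in days.
#' @examples
#' handling_seconds_to_days(16) # ~0.0011
#' @export
handling_seconds_to_days <- function(seconds) {
  if (any(!is.finite(seconds)) || any(seconds < 0))
    stop("handling_seconds_to_days: seconds must be finite and >= 0",
         call. = FALSE)
  seconds / FORAGING_DAY_SECONDS
}

#' Preference exponent from an observed stay probability
#'
#' Inverts the movement model at a 1:1 flower ratio: if a pollinator remains
#' on its current flower sex with probability `stay` when both sexes are
#' equally available, the preference exponent is `log(stay)/log(0.5)`.
#'
#' @param stay Observed probability of remaining on the same flower sex at
#'   equal flower densities, in (0, 1].
#' @return Preference exponent in `[0, Inf)`; values in `[0, 1]` correspond
#'   to a preference to remain (`stay >= 0.5`).
#' @examples
#' preference_from_stay(0.957) # ~0.0634
#' @export
preference_from_stay <- function(stay) {
  if (any(!is.finite(stay)) || any(stay <= 0) || any(stay > 1))
    stop("preference_from_stay: stay must be in (0, 1]", call. = FALSE)
  log(stay) / log(0.5)
}

#' @export
print.flower_params <- function(x, ...) {
  cat("Flower phenology parameters\n")
  cat(sprintf("  male:   %8d buds, peak day %.3g, spread %.3g d, lifespan %.3g d\n",
              round(x$buds_male), x$peak_male, x$spread_male, x$lifespan_male))
  cat(sprintf("  female: %8d buds, peak day %.3g, spread %.3g d, lifespan %.3g d\n",
              round(x$buds_female), x$peak_female, x$spread_female,
              x$lifespan_female))
  invisible(x)
}

#' @export
print.pollinator_params <- function(x, ...) {
  cat("Pollinator parameters\n")
  cat(sprintf("  search rate %.4g /(day.flower), handling time %.4g d (%.1f s)\n",
              x$search_rate, x$handling_time,
              x$handling_time * FORAGING_DAY_SECONDS))
  cat(sprintf("  preference exponents: male %.4g, female %.4g\n",
              x$pref_male, x$pref_female))
  cat(sprintf("  density %.4g per 1000 female buds\n", x$density))
  invisible(x)
}

#' @export
print.fruitset_params <- function(x, ...) {
  cat(sprintf(
    "Per-visit fruit-set probabilities: p1 = %.3g, p2 = %.3g, p3 = %.3g\n",
    x$p1, x$p2, x$p3))
  invisible(x)
}

#' @export
print.scenario <- function(x, ...) {
  cat("Pollination scenario\n")
  print(x$flowers)
  print(x$pollinators)
  print(x$fruitset)
  cat(sprintf("  horizon %.4g d, grid step %.3g d, %s pollinators (basis: %s)\n",
              x$horizon, x$grid_step, format(n_pollinators(x)), x$rho_basis))
  invisible(x)
}
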