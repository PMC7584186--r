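# Parameter-sweep experiments. Every sweep point is an independent full
# simulate_scenario() call; the forward model is deterministic, so sweep
# outputs are reproducible bitwise.

sweep_result <- function(df, grid_cols) {
  i <- which.max(df$total_yield)
  structure(df, class = c("pollination_sweep", "data.frame"),
            grid_cols = grid_cols, argmax = df[i, , drop = FALSE])
}

#' @export
print.pollination_sweep <- function(x, ...) {
  cat(sprintf("Pollination sweep over %s (%d points)\n",
              paste(attr(x, "grid_cols"), collapse = " x "), nrow(x)))
  am <- attr(x, "argmax")
  cat("  yield maximum at:", paste(sprintf("%s = %.4g",
      attr(x, "grid_cols"), unlist(am[attr(x, "grid_cols")])),
      collapse = ", "),
      sprintf("(yield %s, fruit set %.1f%%)\n",
              format(round(am$total_yield), big.mark = ","),
              100 * am$fruit_set))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Argmax row of a sweep
#'
#' @param x A `pollination_sweep`.
#' @return One-row data frame at the yield maximum.
#' @export
sweep_argmax <- function(x) {
  stopifnot(inherits(x, "pollination_sweep"))
  attr(x, "argmax")
}

run_point <- function(sc) {
  sim <- simulate_scenario(sc)
  c(total_yield = sim$total_yield, fruit_set = sim$fruit_set,
    yield_proportion = sim$yield_proportion)
}

# Rebuild a scenario with a modified flower/pollinator/fruitset slot,
# recomputing the default horizon for the new phenology.
swap_params <- function(base, flowers = NULL, pollinators = NULL,
                        fruitset = NULL) {
  scenario(flowers = if (is.null(flowers)) base$flowers else flowers,
           pollinators = if (is.null(pollinators)) base$pollinators
                         else pollinators,
           fruitset = if (is.null(fruitset)) base$fruitset else fruitset,
           horizon = NULL, grid_step = base$grid_step,
           rtol = base$rtol, atol = base$atol, rho_basis = base$rho_basis,
           close_time = base$close_time, accrual_guard = base$accrual_guard)
}

#' Sweep the female fraction of the bud population
#'
#' Varies the fraction of buds that are female while holding the total bud
#' count fixed. By default the absolute pollinator count is held at the base
#' scenario's count (`bees = "base"`): the experiment then isolates the
#' effect of the sex ratio at a fixed bee population, which is how the
#' low-female end can sustain near-complete fruit set. With
#' `bees = "per_female"` the count is re-derived from the density and each
#' point's female bud count instead.
#'
#' After the coarse grid, the neighbourhood of the coarse argmax is refined
#' at `refine_step` resolution (set `refine_step = NULL` to skip).
#'
#' @param fractions Female fractions in (0, 1).
#' @param total_buds Total buds held constant across the sweep.
#' @param base Base [scenario()] supplying all other parameters.
#' @param bees `"base"` (fixed count from `base`) or `"per_female"`.
#' @param refine_step Refinement grid resolution near the coarse argmax.
#' @return A `pollination_sweep` data frame with columns `female_fraction`,
#'   `total_yield`, `fruit_set`, `yield_proportion`.
#' @export
sweep_female_fraction <- function(fractions = seq(0.05, 0.95, by = 0.05),
                                  total_buds = 1.2e6,
                                  base = scenario(),
                                  bees = c("base", "per_female"),
                                  refine_step = 0.01) {
  bees <- match.arg(bees)
  if (any(fractions <= 0) || any(fractions >= 1))
    stop("sweep_female_fraction: fractions must lie strictly in (0, 1)",
         call. = FALSE)
  base_count <- n_pollinators(base)
  point <- function(fr) {
    bf <- fr * total_buds
    fl <- base$flowers
    fl2 <- flower_params(buds_male = total_buds - bf, buds_female = bf,
                         peak_male = fl$peak_male,
                         peak_female = fl$peak_female,
                         spread_male = fl$spread_male,
                         spread_female = fl$spread_female,
                         lifespan_male = fl$lifespan_male,
                         lifespan_female = fl$lifespan_female)
    po <- base$pollinators
    dens <- if (bees == "base") 1000 * base_count / bf else po$density
    po2 <- pollinator_params(search_rate = po$search_rate,
                             handling_time = po$handling_time,
                             pref_male = po$pref_male,
                             pref_female = po$pref_female,
                             density = dens)
    sc <- swap_params(base, flowers = fl2, pollinators = po2)
    sc$rho_basis <- "per_female"  # density above already encodes the basis
    run_point(sc)
  }
  grid <- sort(unique(fractions))
  res <- t(vapply(grid, point, numeric(3)))
  if (!is.null(refine_step) && length(grid) > 1) {
    i <- which.max(res[, "total_yield"])
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    extra <- setdiff(round(seq(lo, hi, by = refine_step), 10), grid)
    if (length(extra)) {
      res2 <- t(vapply(extra, point, numeric(3)))
      grid <- c(grid, extra)
      res <- rbind(res, res2)
      o <- order(grid)
      grid <- grid[o]
      res <- res[o, , drop = FALSE]
    }
  }
  sweep_result(data.frame(female_fraction = grid, res),
               "female_fraction")
}

#' Sweep pollinator density
#'
#' @param densities Pollinators per 1000 female buds.
#' @param base Base [scenario()].
#' @return A `pollination_sweep` with column `density`.
#' @export
sweep_bee_density <- function(densities = 1:20, base = scenario()) {
  if (any(densities <= 0))
    stop("sweep_bee_density: densities must be > 0", call. = FALSE)
  point <- function(d) {
    po <- base$pollinators
    po2 <- pollinator_params(search_rate = po$search_rate,
                             handling_time = po$handling_time,
                             pref_male = po$pref_male,
                             pref_female = po$pref_female, density = d)
    run_point(swap_params(base, pollinators = po2))
  }
  grid <- sort(unique(densities))
  res <- t(vapply(grid, point, numeric(3)))
  sweep_result(data.frame(density = grid, res), "density")
}

#' Sweep the male bloom peak day
#'
#' Shifts the male opening-rate peak while the female peak stays at the base
#' scenario's value, changing how much of the bloom the sexes overlap.
#'
#' @param peaks Male peak days.
#' @param base Base [scenario()].
#' @return A `pollination_sweep` with column `peak_male`.
#' @export
sweep_male_peak <- function(peaks = 3:9, base = scenario()) {
  if (any(peaks < 0))
    stop("sweep_male_peak: peaks must be >= 0", call. = FALSE)
  point <- function(pk) {
    fl <- base$flowers
    fl2 <- flower_params(buds_male = fl$buds_male,
                         buds_female = fl$buds_female,
                         peak_male = pk, peak_female = fl$peak_female,
                         spread_male = fl$spread_male,
                         spread_female = fl$spread_female,
                         lifespan_male = fl$lifespan_male,
                         lifespan_female = fl$lifespan_female)
    run_point(swap_params(base, flowers = fl2))
  }
  grid <- sort(unique(peaks))
  res <- t(vapply(grid, point, numeric(3)))
  sweep_result(data.frame(peak_male = grid, res), "peak_male")
}

#' Sweep the preference exponents
#'
#' @param values Preference exponents in `[0, 1]`. Small values mean strong
#'   tendencies to remain on the current flower sex; 1 means no preference.
#' @param which Apply the swept value to the male exponent, the female
#'   exponent, or both.
#' @param base Base [scenario()].
#' @return A `pollination_sweep` with column `preference`.
#' @export
sweep_preference <- function(values = seq(0, 1, by = 0.02),
                             which = c("both", "male", "female"),
                             base = scenario()) {
  which <- match.arg(which)
  if (any(values < 0) || any(values > 1))
    stop("sweep_preference: values must lie in [0, 1]", call. = FALSE)
  point <- function(v) {
    po <- base$pollinators
    po2 <- pollinator_params(
      search_rate = po$search_rate, handling_time = po$handling_time,
      pref_male = if (which %in% c("both", "male")) v else po$pref_male,
      pref_female = if (which %in% c("both", "female")) v else po$pref_female,
      density = po$density)
    run_point(swap_params(base, pollinators = po2))
  }
  grid <- sort(unique(values))
  res <- t(vapply(grid, point, numeric(3)))
  sweep_result(data.frame(preference = grid, res), "preference")
}

#' Sweep the handling time
#'
#' @param seconds Handling times in seconds of the active foraging day;
#'   converted internally via [handling_seconds_to_days()].
#' @param base Base [scenario()].
#' @return A `pollination_sweep` with columns `handling_seconds` and
#'   `handling_days`.
#' @export
sweep_handling_time <- function(seconds = seq(5, 120, by = 5),
                                base = scenario()) {
  betas <- handling_seconds_to_days(seconds)
  point <- function(b) {
    po <- base$pollinators
    po2 <- pollinator_params(search_rate = po$search_rate,
                             handling_time = b,
                             pref_male = po$pref_male,
                             pref_female = po$pref_female,
                             density = po$density)
    run_point(swap_params(base, pollinators = po2))
  }
  o <- order(seconds)
  grid_s <- seconds[o]; grid_b <- betas[o]
  res <- t(vapply(grid_b, point, numeric(3)))
  sweep_result(data.frame(handling_seconds = grid_s,
                          handling_days = grid_b, res),
               "handling_seconds")
}

#' Female fraction x pollinator density yield surface
#'
#' Crosses the female-fraction sweep with the bee-density sweep. Here the
#' density axis is pollinators per 1000 female buds at each point (the count
#' co-varies with the fraction), so a column of the surface at the fraction
#' matching the base scenario reproduces [sweep_bee_density()], and a row
#' reproduces [sweep_female_fraction()] run with `bees = "per_female"`.
#'
#' @param fractions Female fractions in (0, 1).
#' @param densities Pollinators per 1000 female buds.
#' @param total_buds Total buds held constant.
#' @param base Base [scenario()].
#' @return A `pollination_sweep` in long format with columns
#'   `female_fraction`, `density`, `total_yield`, `fruit_set`,
#'   `yield_proportion`, plus a `yield_matrix` attribute
#'   (fractions x densities).
#' @export
surface_female_by_density <- function(fractions = seq(0.1, 0.9, by = 0.1),
                                      densities = c(2, 4, 6, 10, 15, 20),
                                      total_buds = 1.2e6,
                                      base = scenario()) {
  if (any(fractions <= 0) || any(fractions >= 1))
    stop("surface_female_by_density: fractions must lie in (0, 1)",
         call. = FALSE)
  if (any(densities <= 0))
    stop("surface_female_by_density: densities must be > 0", call. = FALSE)
  fractions <- sort(unique(fractions))
  densities <- sort(unique(densities))
  grid <- expand.grid(female_fraction = fractions, density = densities,
                      KEEP.OUT.ATTRS = FALSE)
  point <- function(fr, d) {
    bf <- fr * total_buds
    fl <- base$flowers
    fl2 <- flower_params(buds_male = total_buds - bf, buds_female = bf,
                         peak_male = fl$peak_male,
                         peak_female = fl$peak_female,
                         spread_male = fl$spread_male,
                         spread_female = fl$spread_female,
                         lifespan_male = fl$lifespan_male,
                         lifespan_female = fl$lifespan_female)
    po <- base$pollinators
    po2 <- pollinator_params(search_rate = po$search_rate,
                             handling_time = po$handling_time,
                             pref_male = po$pref_male,
                             pref_female = po$pref_female, density = d)
    sc <- swap_params(base, flowers = fl2, pollinators = po2)
    sc$rho_basis <- "per_female"
    run_point(sc)
  }
  res <- t(mapply(point, grid$female_fraction, grid$density))
  out <- sweep_result(data.frame(grid, res),
                      c("female_fraction", "density"))
  attr(out, "yield_matrix") <- matrix(
    out$total_yield, nrow = length(fractions),
    dimnames = list(female_fraction = fractions, density = densities))
  out
}

#' Write a sweep to CSV
#'
#' One row per grid point; re-reading with [read.csv()] reproduces the
#' numeric content.
#'
#' @param x A `pollination_sweep`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(x, path) {
  stopifnot(inherits(x, "pollination_sweep"))
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
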