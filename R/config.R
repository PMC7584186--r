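# Configuration: a flat YAML key-value block mirroring the model parameter
# names, plus run controls. An empty document is the baseline scenario.

CONFIG_PARAM_KEYS <- c(
  "alpha", "beta", "delta", "epsilon", "B_m", "B_f", "t_m", "t_f",
  "sigma_m", "sigma_f", "tau_m", "tau_f", "rho", "p1", "p2", "p3")
CONFIG_CONTROL_KEYS <- c(
  "handling_seconds", "horizon", "grid_step", "rtol", "atol", "rho_basis",
  "close_time", "accrual_guard", "seed")

# Plausibility ranges used for soft validation (warnings) of configs; these
# mirror the sensitivity-analysis sampling ranges, widened to include the
# degenerate-but-valid low end (e.g. rho = 0).
CONFIG_PLAUSIBLE <- list(
  alpha = c(120, 3600), beta = c(0, 0.0094), delta = c(0, 1),
  epsilon = c(0, 1), B_m = c(0, 5e6), B_f = c(0, 5e6),
  t_m = c(0, 9), t_f = c(0, 9), sigma_m = c(0.5, 5.5),
  sigma_f = c(0.5, 5.5), tau_m = c(1, 7), tau_f = c(1, 7),
  rho = c(0, 20), p1 = c(0, 1), p2 = c(0, 1), p3 = c(0, 1))

#' Load a scenario from a YAML config
#'
#' Reads a flat YAML document of parameter overrides and run controls and
#' returns a fully validated [scenario()]. Unspecified keys take the
#' baseline values. Recognised parameter keys: `alpha` (search rate),
#' `beta` (handling time, days) or `handling_seconds`, `delta`/`epsilon`
#' (preference exponents), `B_m`/`B_f` (bud counts), `t_m`/`t_f` (peak
#' days), `sigma_m`/`sigma_f` (spreads), `tau_m`/`tau_f` (lifespans),
#' `rho` (density), `p1`/`p2`/`p3`; run controls: `horizon`, `grid_step`,
#' `rtol`, `atol`, `rho_basis`, `close_time`, `accrual_guard`, `seed`.
#'
#' @param path Path to a YAML file, or `NULL`.
#' @param overrides Named list merged over the file's values (useful for
#'   command-line flags).
#' @param allow_out_of_range If `FALSE` (default) values outside the
#'   plausible parameter ranges trigger a warning.
#' @return A [scenario()], with the config's `seed` (if any) attached as
#'   attribute `seed`.
#' @export
load_config <- function(path = NULL, overrides = list(),
                        allow_out_of_range = FALSE) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("load_config: no such file: ", path, call. = FALSE)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  cfg <- modifyList(cfg, overrides)
  known <- c(CONFIG_PARAM_KEYS, CONFIG_CONTROL_KEYS)
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("load_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$handling_seconds)) {
    if (!is.null(cfg$beta))
      stop("load_config: give either `beta` or `handling_seconds`, not both",
         call. = FALSE)
    cfg$beta <- handling_seconds_to_days(cfg$handling_seconds)
  }
  if (!allow_out_of_range) {
    for (nm in intersect(names(cfg), names(CONFIG_PLAUSIBLE))) {
      r <- CONFIG_PLAUSIBLE[[nm]]
      v <- cfg[[nm]]
      if (is.numeric(v) && (v < r[1] || v > r[2]))
        warning("load_config: `", nm, "` = ", v,
                " is outside the plausible range [", r[1], ", ", r[2],
                "]", call. = FALSE)
    }
  }
  g <- function(nm, default) if (is.null(cfg[[nm]])) default else cfg[[nm]]
  fl <- flower_params(
    buds_male = g("B_m", 600000), buds_female = g("B_f", 600000),
    peak_male = g("t_m", 6), peak_female = g("t_f", 6),
    spread_male = g("sigma_m", 2.5), spread_female = g("sigma_f", 2),
    lifespan_male = g("tau_m", 4), lifespan_female = g("tau_f", 5))
  po <- pollinator_params(
    search_rate = g("alpha", 480), handling_time = g("beta", 0.0011),
    pref_male = g("delta", preference_from_stay(0.957)),
    pref_female = g("epsilon", preference_from_stay(0.951)),
    density = g("rho", 6))
  fs <- fruitset_params(p1 = g("p1", 0.66), p2 = g("p2", 0.55),
                        p3 = g("p3", 0.22))
  sc <- scenario(flowers = fl, pollinators = po, fruitset = fs,
                 horizon = g("horizon", NULL),
                 grid_step = g("grid_step", 0.01),
                 rtol = g("rtol", 1e-8), atol = g("atol", 1e-6),
                 rho_basis = g("rho_basis", "per_female"),
                 close_time = g("close_time", "weighted"),
                 accrual_guard = g("accrual_guard", 1e-6))
  attr(sc, "seed") <- cfg$seed
  sc
}

#' Serialize a scenario back to the flat config key set
#'
#' Inverse of [load_config()]: `load_config(overrides = dump_config(sc))`
#' reproduces `sc`.
#'
#' @param sc A [scenario()].
#' @return Named list using the config key names.
#' @export
dump_config <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  fl <- sc$flowers; po <- sc$pollinators; fs <- sc$fruitset
  list(alpha = po$search_rate, beta = po$handling_time,
       delta = po$pref_male, epsilon = po$pref_female,
       B_m = fl$buds_male, B_f = fl$buds_female,
       t_m = fl$peak_male, t_f = fl$peak_female,
       sigma_m = fl$spread_male, sigma_f = fl$spread_female,
       tau_m = fl$lifespan_male, tau_f = fl$lifespan_female,
       rho = po$density, p1 = fs$p1, p2 = fs$p2, p3 = fs$p3,
       horizon = sc$horizon, grid_step = sc$grid_step,
       rtol = sc$rtol, atol = sc$atol, rho_basis = sc$rho_basis,
       close_time = sc$close_time, accrual_guard = sc$accrual_guard)
}

#' Prebuilt study scenarios and sweep specifications
#'
#' Named fixtures for the standard numerical experiments:
#' \describe{
#'   \item{`baseline`}{the base 1-ha scenario (equal 600,000 male and female
#'     buds, 6 bees per 1000 female buds): returns a [scenario()].}
#'   \item{`female_fraction`}{sex-ratio sweep at 1.2 million total buds,
#'     fractions 0.05-0.95 (coarse) with 0.01 refinement, bee count fixed at
#'     the baseline's 3600.}
#'   \item{`male_peak`}{male peak day 3-9 with the female peak at day 6.}
#'   \item{`bee_density`}{1-20 bees per 1000 female buds.}
#'   \item{`preference`}{both preference exponents swept over 0-1.}
#'   \item{`handling_time`}{handling time 5-120 s.}
#'   \item{`female_by_density`}{the female-fraction x density surface.}
#' }
#' Sweep fixtures return a `sweep_spec`: a list with the sweep function
#' name, its arguments, and the base scenario; run it with [run_sweep()].
#'
#' @param name Fixture name.
#' @param base Base scenario (default the baseline).
#' @return A [scenario()] (for `baseline`) or a `sweep_spec`.
#' @examples
#' scenario_fixture("baseline")$flowers$buds_male
#' @export
scenario_fixture <- function(name = c("baseline", "female_fraction",
                                      "male_peak", "bee_density",
                                      "preference", "handling_time",
                                      "female_by_density"),
                             base = scenario()) {
  name <- match.arg(name)
  spec <- function(fn, args) structure(list(fn = fn, args = args,
                                            base = base, name = name),
                                       class = "sweep_spec")
  switch(name,
    baseline = base,
    female_fraction = spec("sweep_female_fraction",
                           list(fractions = seq(0.05, 0.95, by = 0.05),
                                total_buds = 1.2e6, bees = "base",
                                refine_step = 0.01)),
    male_peak = spec("sweep_male_peak", list(peaks = 3:9)),
    bee_density = spec("sweep_bee_density", list(densities = 1:20)),
    preference = spec("sweep_preference",
                      list(values = seq(0, 1, by = 0.02), which = "both")),
    handling_time = spec("sweep_handling_time",
                         list(seconds = seq(5, 120, by = 5))),
    female_by_density = spec("surface_female_by_density",
                             list(fractions = seq(0.1, 0.9, by = 0.1),
                                  densities = c(2, 4, 6, 10, 15, 20),
                                  total_buds = 1.2e6)))
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat("Sweep specification:", x$name, "->", x$fn, "\n")
  utils::str(x$args, give.attr = FALSE)
  invisible(x)
}

#' Run a sweep specification
#'
#' @param spec A `sweep_spec` from [scenario_fixture()].
#' @return The corresponding `pollination_sweep`.
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  do.call(spec$fn, c(spec$args, list(base = spec$base)))
}
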