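# Global sensitivity analysis: Latin hypercube sampling over the plausible
# parameter ranges, partial rank correlation coefficients (PRCC) of total
# predicted yield against each parameter, significance tests, and a
# monotonicity screen with truncated-range re-analysis for parameters whose
# relationship with yield is not monotone.

#' Plausible parameter ranges for sensitivity analysis
#'
#' The sampled parameter space. Two bases are available for the bud
#' parameters: `"composition"` (default) samples the total bud count and the
#' fraction of buds that are female -- the quantities the analysis reports
#' on -- while `"raw"` samples the male and female bud counts independently.
#' Note the raw basis confines the female fraction to `[0.25, 0.75]`, so the
#' composition basis is required to probe female-dominated orchards.
#'
#' @param basis `"composition"` or `"raw"`.
#' @return Data frame with columns `name`, `low`, `high`.
#' @export
parameter_ranges <- function(basis = c("composition", "raw")) {
  basis <- match.arg(basis)
  common <- list(
    search_rate = c(120, 3600),
    handling_time = c(0.00013, 0.0094),
    pref_male = c(0, 1),
    pref_female = c(0, 1),
    peak_male = c(2, 9),
    peak_female = c(2, 9),
    spread_male = c(0.5, 5.5),
    spread_female = c(1, 4),
    lifespan_male = c(3, 5),
    lifespan_female = c(3, 7),
    density = c(1, 20),
    p1 = c(0.25, 0.75),
    p2 = c(0.1, 0.65),
    p3 = c(0, 0.5)
  )
  buds <- if (basis == "composition") {
    list(total_buds = c(6e5, 1.8e6), pct_female = c(0.05, 0.96))
  } else {
    list(buds_male = c(3e5, 9e5), buds_female = c(3e5, 9e5))
  }
  ranges <- c(buds, common)
  out <- data.frame(name = names(ranges),
                    low = vapply(ranges, `[`, numeric(1), 1),
                    high = vapply(ranges, `[`, numeric(1), 2),
                    row.names = NULL)
  attr(out, "basis") <- basis
  out
}

#' Latin hypercube sample over parameter ranges
#'
#' Stratified uniform sampling: each parameter's range is divided into `n`
#' equiprobable strata and each stratum receives exactly one draw.
#'
#' @param ranges Data frame from [parameter_ranges()] (or with the same
#'   columns).
#' @param n Number of design rows (strata per parameter). PRCC downstream
#'   additionally needs `n > k + 2`.
#' @param seed Integer seed; the design is reproducible given the seed.
#' @return Object of class `lhs_design`: list with `samples` (n x k matrix,
#'   named columns), `unit` (the underlying unit-cube design), `ranges`,
#'   `seed`.
#' @export
lhs_sample <- function(ranges, n, seed) {
  if (any(ranges$high <= ranges$low))
    stop("lhs_sample: degenerate range for ",
         paste(ranges$name[ranges$high <= ranges$low], collapse = ", "),
         call. = FALSE)
  k <- nrow(ranges)
  if (n < 2)
    stop("lhs_sample: need n >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  unit <- lhs::randomLHS(n, k)
  samples <- sweep(unit, 2, ranges$high - ranges$low, `*`)
  samples <- sweep(samples, 2, ranges$low, `+`)
  colnames(samples) <- colnames(unit) <- ranges$name
  structure(list(samples = samples, unit = unit, ranges = ranges,
                 seed = as.integer(seed)),
            class = "lhs_design")
}

#' Build a scenario from one sampled parameter row
#'
#' @param draw Named numeric vector (one row of an `lhs_design`'s samples).
#' @param base Base [scenario()] supplying numerical controls and any
#'   parameter the draw does not override.
#' @return A [scenario()].
#' @export
scenario_from_draw <- function(draw, base = scenario()) {
  g <- function(nm, default) if (nm %in% names(draw)) draw[[nm]] else default
  if ("total_buds" %in% names(draw) || "pct_female" %in% names(draw)) {
    tot <- g("total_buds", base$flowers$buds_male + base$flowers$buds_female)
    pf <- g("pct_female",
            base$flowers$buds_female /
              (base$flowers$buds_male + base$flowers$buds_female))
    bf <- pf * tot
    bm <- tot - bf
  } else {
    bm <- g("buds_male", base$flowers$buds_male)
    bf <- g("buds_female", base$flowers$buds_female)
  }
  fl <- flower_params(
    buds_male = bm, buds_female = bf,
    peak_male = g("peak_male", base$flowers$peak_male),
    peak_female = g("peak_female", base$flowers$peak_female),
    spread_male = g("spread_male", base$flowers$spread_male),
    spread_female = g("spread_female", base$flowers$spread_female),
    lifespan_male = g("lifespan_male", base$flowers$lifespan_male),
    lifespan_female = g("lifespan_female", base$flowers$lifespan_female))
  po <- pollinator_params(
    search_rate = g("search_rate", base$pollinators$search_rate),
    handling_time = g("handling_time", base$pollinators$handling_time),
    pref_male = g("pref_male", base$pollinators$pref_male),
    pref_female = g("pref_female", base$pollinators$pref_female),
    density = g("density", base$pollinators$density))
  fs <- fruitset_params(p1 = g("p1", base$fruitset$p1),
                        p2 = g("p2", base$fruitset$p2),
                        p3 = g("p3", base$fruitset$p3))
  scenario(flowers = fl, pollinators = po, fruitset = fs,
           horizon = NULL, grid_step = base$grid_step, rtol = base$rtol,
           atol = base$atol, rho_basis = base$rho_basis,
           close_time = base$close_time,
           accrual_guard = base$accrual_guard)
}

#' Run the model over a sampled design
#'
#' One full simulation per design row. Failed rows are recorded (with their
#' error message) rather than silently dropped; more than 1% failures aborts
#' the batch.
#'
#' @param design An `lhs_design` (or any matrix with named columns).
#' @param base Base [scenario()].
#' @return Numeric vector of total predicted yields, one per row (`NA` for
#'   failed rows), with a `failures` attribute (data frame `row`,
#'   `message`).
#' @export
run_batch <- function(design, base = scenario()) {
  samples <- if (inherits(design, "lhs_design")) design$samples else design
  n <- nrow(samples)
  yields <- rep(NA_real_, n)
  fail_row <- integer(0)
  fail_msg <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch(
      simulate_scenario(scenario_from_draw(samples[i, ], base))$total_yield,
      error = function(e) e)
    if (inherits(res, "error")) {
      fail_row <- c(fail_row, i)
      fail_msg <- c(fail_msg, conditionMessage(res))
    } else {
      yields[i] <- res
    }
  }
  if (length(fail_row) > 0.01 * n)
    stop("run_batch: ", length(fail_row), "/", n, " rows failed; first: ",
         fail_msg[1], call. = FALSE)
  attr(yields, "failures") <- data.frame(row = fail_row, message = fail_msg)
  yields
}

# Residuals of a rank-transformed column regressed on all other
# rank-transformed columns (with intercept).
rank_residuals <- function(y, X) {
  fit <- lm.fit(cbind(1, X), y)
  fit$residuals
}

#' Partial rank correlation coefficients
#'
#' For each parameter, all columns and the output are rank-transformed
#' (average ranks on ties); the PRCC is the correlation between the
#' residuals of the parameter's ranks and of the output's ranks after
#' regressing each on the ranks of all other parameters. Significance uses
#' the statistic `prcc * sqrt((n - 2 - k) / (1 - prcc^2))` with `k` the
#' number of parameters, referred to both a Student-t null
#' (`p_t`, used for the `significant` flag) and a standard normal (`p_z`).
#'
#' @param samples Numeric matrix (n x k, named columns) of parameter draws,
#'   or an `lhs_design`.
#' @param output Numeric vector of model outputs, length n. Rows with `NA`
#'   output are dropped.
#' @param alpha Significance level for the `significant` flag.
#' @return Data frame of class `prcc_report`: `parameter`, `prcc`,
#'   `statistic`, `p_t`, `p_z`, `significant`.
#' @export
prcc <- function(samples, output, alpha = 0.05) {
  if (inherits(samples, "lhs_design")) samples <- samples$samples
  keep <- !is.na(output)
  samples <- samples[keep, , drop = FALSE]
  output <- output[keep]
  n <- nrow(samples)
  k <- ncol(samples)
  if (n <= k + 2)
    stop("prcc: need more rows than parameters + 2", call. = FALSE)
  if (any(apply(samples, 2, function(x) length(unique(x)) < 2)))
    stop("prcc: constant parameter column", call. = FALSE)
  if (length(unique(output)) < 2)
    stop("prcc: constant output", call. = FALSE)
  R <- apply(samples, 2, rank)
  ry <- rank(output)
  vals <- vapply(seq_len(k), function(j) {
    e_x <- rank_residuals(R[, j], R[, -j, drop = FALSE])
    e_y <- rank_residuals(ry, R[, -j, drop = FALSE])
    if (sd(e_x) == 0 || sd(e_y) == 0)
      stop("prcc: rank degeneracy in column ", colnames(R)[j],
           call. = FALSE)
    cor(e_x, e_y)
  }, numeric(1))
  df <- n - 2 - k
  stat <- vals * sqrt(df / pmax(1 - vals^2, .Machine$double.eps))
  p_t <- 2 * pt(-abs(stat), df = df)
  p_z <- 2 * pnorm(-abs(stat))
  structure(data.frame(parameter = colnames(samples), prcc = vals,
                       statistic = stat, p_t = p_t, p_z = p_z,
                       significant = p_t < alpha, row.names = NULL),
            class = c("prcc_report", "data.frame"),
            n = n, alpha = alpha)
}

#' @importFrom stats sd
#' @export
print.prcc_report <- function(x, ...) {
  cat(sprintf("PRCC report (n = %d, alpha = %g)\n",
              attr(x, "n"), attr(x, "alpha")))
  df <- as.data.frame(x)
  df <- df[order(-abs(df$prcc)), ]
  df$prcc <- round(df$prcc, 3)
  df$statistic <- round(df$statistic, 2)
  df$p_t <- signif(df$p_t, 3)
  df$p_z <- signif(df$p_z, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Monotonicity screen for one parameter
#'
#' PRCC assumes a monotone parameter-output relationship. This screen bins
#' the parameter into `bins` equal-count bins, smooths the bin-mean outputs
#' with a 3-point moving average, and flags the relationship nonmonotone if
#' both the total upward and total downward movement of the smoothed means
#' exceed 10% of their range. For a nonmonotone parameter a split point at
#' the edge of the extremum bin is proposed, so the range can be cut into
#' monotone pieces for truncated re-analysis.
#'
#' @param samples Matrix of draws (or `lhs_design`).
#' @param output Output vector (NA rows dropped).
#' @param parameter Column name to screen.
#' @param bins Number of equal-count bins (default 10, i.e. deciles).
#' @return List: `monotone` (flag), `split` (proposed split value, `NULL`
#'   if monotone), `bin_mid`, `bin_mean`, `bin_mean_smooth`.
#' @export
monotonicity_check <- function(samples, output, parameter, bins = 10) {
  if (inherits(samples, "lhs_design")) samples <- samples$samples
  keep <- !is.na(output)
  x <- samples[keep, parameter]
  y <- output[keep]
  qs <- quantile(x, probs = seq(0, 1, length.out = bins + 1), names = FALSE)
  idx <- findInterval(x, qs, rightmost.closed = TRUE, all.inside = TRUE)
  bin_mean <- tapply(y, idx, mean)
  bin_mid <- tapply(x, idx, mean)
  sm <- stats::filter(bin_mean, rep(1 / 3, 3), sides = 2)
  sm[1] <- mean(bin_mean[1:2])
  sm[bins] <- mean(bin_mean[(bins - 1):bins])
  sm <- as.numeric(sm)
  d <- diff(sm)
  up <- sum(pmax(d, 0)); down <- sum(pmax(-d, 0))
  rng <- diff(range(sm))
  monotone <- rng == 0 || min(up, down) <= 0.1 * rng
  split <- NULL
  if (!monotone) {
    j <- if (up >= down) which.max(sm) else which.min(sm)
    j <- min(max(j, 1L), bins)
    # split at the outer edge of the extremum bin, in the direction the
    # curve was heading
    split <- unname(qs[j + 1])
  }
  list(monotone = monotone, split = split,
       bin_mid = as.numeric(bin_mid), bin_mean = as.numeric(bin_mean),
       bin_mean_smooth = sm)
}

#' PRCC over truncated parameter windows
#'
#' Re-runs the full sampling + simulation + PRCC pipeline with one or more
#' parameter ranges truncated to a monotone window, as a follow-up for
#' parameters flagged by [monotonicity_check()].
#'
#' @param windows Named list of length-2 numeric vectors, e.g.
#'   `list(pct_female = c(0.05, 0.76))`. Windows must lie within the
#'   original ranges.
#' @param ranges Full [parameter_ranges()] to truncate.
#' @param n Design size.
#' @param seed Seed for the truncated design.
#' @param base Base [scenario()].
#' @return A `prcc_report` with attributes `windows` and `yields`.
#' @export
truncated_prcc <- function(windows, ranges = parameter_ranges(), n, seed,
                           base = scenario()) {
  r2 <- ranges
  for (nm in names(windows)) {
    i <- match(nm, r2$name)
    if (is.na(i)) stop("truncated_prcc: unknown parameter ", nm,
                       call. = FALSE)
    w <- windows[[nm]]
    if (w[1] < r2$low[i] - 1e-12 || w[2] > r2$high[i] + 1e-12 ||
        w[2] <= w[1])
      stop("truncated_prcc: window for ", nm,
           " must be an increasing interval within the original range",
           call. = FALSE)
    r2$low[i] <- w[1]
    r2$high[i] <- w[2]
  }
  design <- lhs_sample(r2, n, seed)
  yields <- run_batch(design, base)
  rep <- prcc(design, yields)
  attr(rep, "windows") <- windows
  attr(rep, "yields") <- yields
  rep
}

#' Full sensitivity analysis
#'
#' Convenience pipeline: LHS design, batch run, PRCC, monotonicity screen
#' for every parameter, and (optionally) truncated re-analyses for the
#' female-fraction windows either side of its yield optimum.
#'
#' @param n Design size.
#' @param seed Integer seed.
#' @param base Base [scenario()].
#' @param ranges Parameter ranges (default [parameter_ranges()]).
#' @param truncate If `TRUE`, run truncated re-analyses for `pct_female`
#'   below and above its proposed split.
#' @return List with `design`, `yields`, `prcc` (full-range report with a
#'   `monotone` column), `monotonicity` (per-parameter screen results) and,
#'   if requested, `truncated` (list of `prcc_report`s).
#' @export
sensitivity_analysis <- function(n = 1000, seed = 1, base = scenario(),
                                 ranges = parameter_ranges(),
                                 truncate = FALSE) {
  design <- lhs_sample(ranges, n, seed)
  yields <- run_batch(design, base)
  rep <- prcc(design, yields)
  mono <- lapply(setNames(ranges$name, ranges$name), function(nm)
    monotonicity_check(design, yields, nm))
  rep$monotone <- vapply(mono[rep$parameter], `[[`, logical(1), "monotone")
  out <- list(design = design, yields = yields, prcc = rep,
              monotonicity = mono)
  if (truncate && "pct_female" %in% ranges$name) {
    split <- mono$pct_female$split
    if (is.null(split)) split <- 0.76
    lo <- ranges$low[ranges$name == "pct_female"]
    hi <- ranges$high[ranges$name == "pct_female"]
    out$truncated <- list(
      pct_female_low = truncated_prcc(list(pct_female = c(lo, split)),
                                      ranges, n, seed + 1L, base),
      pct_female_high = truncated_prcc(list(pct_female = c(split, hi)),
                                       ranges, n, seed + 2L, base))
  }
  out
}
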