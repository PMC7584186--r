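# Independent oracles used across the test files. These deliberately avoid
# the package's closed-form / adaptive-solver code paths.

# Cumulative openings by adaptive quadrature of the Gaussian opening rate.
quad_cumulative <- function(t, buds, peak, spread) {
  if (t <= 0) return(0)
  rate <- function(s) buds / sqrt(2 * pi * spread^2) *
    exp(-(s - peak)^2 / (2 * spread^2))
  stats::integrate(rate, 0, t, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# A fast set of numerical controls for scenarios used in bulk property
# tests (coarser grid and looser tolerances; the asserted properties are
# structural, not high-precision).
fast_controls <- function(sc) {
  sc$grid_step <- 0.05
  sc$rtol <- 1e-6
  sc$atol <- 1e-4
  sc
}

# Scenario with parameters drawn uniformly within the plausible ranges.
random_table_scenario <- function() {
  r <- function(lo, hi) stats::runif(1, lo, hi)
  fl <- flower_params(
    buds_male = r(3e5, 9e5), buds_female = r(3e5, 9e5),
    peak_male = r(2, 9), peak_female = r(2, 9),
    spread_male = r(0.5, 5.5), spread_female = r(1, 4),
    lifespan_male = r(3, 5), lifespan_female = r(3, 7))
  po <- pollinator_params(
    search_rate = r(120, 3600), handling_time = r(0.00013, 0.0094),
    pref_male = r(0, 1), pref_female = r(0, 1), density = r(1, 20))
  fs <- fruitset_params(p1 = r(0.25, 0.75), p2 = r(0.1, 0.65),
                        p3 = r(0, 0.5))
  fast_controls(scenario(flowers = fl, pollinators = po, fruitset = fs))
}

# Plain-formula right-hand side of the coupled system (independent of the
# package's internal rhs closure).
oracle_rhs <- function(t, y, sc) {
  fl <- sc$flowers; po <- sc$pollinators
  cum <- function(tt, B, pk, s) {
    out <- B * (pnorm((tt - pk) / s) - pnorm(-pk / s))
    if (tt <= 0) 0 else max(out, 0)
  }
  m <- cum(t, fl$buds_male, fl$peak_male, fl$spread_male) -
    cum(t - fl$lifespan_male, fl$buds_male, fl$peak_male, fl$spread_male)
  f <- cum(t, fl$buds_female, fl$peak_female, fl$spread_female) -
    cum(t - fl$lifespan_female, fl$buds_female, fl$peak_female,
        fl$spread_female)
  tot <- m + f
  V <- po$search_rate * tot / (1 + po$search_rate * po$handling_time * tot)
  if (tot > 0) {
    sm <- (m / tot)^po$pref_male
    sf <- (f / tot)^po$pref_female
  } else {
    sm <- 1; sf <- 1
  }
  r1 <- V * (1 - sm) * y[1]
  r2 <- V * sf * y[2]
  r3 <- V * sf * y[3]
  tm <- V * (1 - sf)
  g <- if (f > sc$accrual_guard) 1 / f else 0
  c(tm * (y[2] + y[3] + y[4]) - r1,
    r1 - tm * y[2] - r2,
    r2 - tm * y[3] - r3,
    r3 - tm * y[4],
    r1 * g, r2 * g, r3 * g)
}

# Rebuild the daily yield table from accrual columns on a time grid, using
# the cohort rule (exposure window of one female lifespan, evaluated at the
# closing day's midpoint).
oracle_daily_yield <- function(times, A, sc) {
  fl <- sc$flowers
  days <- seq_len(floor(sc$horizon)) - 1L
  t_close <- pmin(days + 0.5, sc$horizon)
  A_at <- function(col, tq) {
    out <- stats::approx(times, A[, col], xout = pmax(tq, 0), rule = 2)$y
    out[tq <= 0] <- 0
    out
  }
  tau <- fl$lifespan_female
  v1 <- pmax(A_at(1, t_close) - A_at(1, t_close - tau), 0)
  v2 <- pmax(A_at(2, t_close) - A_at(2, t_close - tau), 0)
  v3 <- pmax(A_at(3, t_close) - A_at(3, t_close - tau), 0)
  dfc <- daily_female_closing(days, fl)
  P <- 1 - (1 - sc$fruitset$p1)^v1 * (1 - sc$fruitset$p2)^v2 *
    (1 - sc$fruitset$p3)^v3
  sum(dfc * P)
}

# Classical fixed-step 4th-order Runge-Kutta integration of the coupled
# system, followed by the cohort accounting. Independent of deSolve.
rk4_yield <- function(sc, h = 0.001) {
  n_steps <- ceiling(sc$horizon / h)
  y <- c(0, 0, 0, n_pollinators(sc), 0, 0, 0)
  times <- numeric(n_steps + 1)
  A <- matrix(0, n_steps + 1, 3)
  t <- 0
  for (i in seq_len(n_steps)) {
    k1 <- oracle_rhs(t, y, sc)
    k2 <- oracle_rhs(t + h / 2, y + h / 2 * k1, sc)
    k3 <- oracle_rhs(t + h / 2, y + h / 2 * k2, sc)
    k4 <- oracle_rhs(t + h, y + h * k3, sc)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    times[i + 1] <- t
    A[i + 1, ] <- y[5:7]
  }
  oracle_daily_yield(times, A, sc)
}

# Literal delay formulation: the cumulative bloom curves M and F are solved
# as ODE states and the open counts use lagged state values (method of
# steps via deSolve::dede), rather than the closed-form forcing.
dde_yield <- function(sc) {
  fl <- sc$flowers; po <- sc$pollinators
  rhs <- function(t, y, parms) {
    dM <- fl$buds_male / sqrt(2 * pi * fl$spread_male^2) *
      exp(-(t - fl$peak_male)^2 / (2 * fl$spread_male^2))
    dF <- fl$buds_female / sqrt(2 * pi * fl$spread_female^2) *
      exp(-(t - fl$peak_female)^2 / (2 * fl$spread_female^2))
    M_lag <- if (t > fl$lifespan_male)
      deSolve::lagvalue(t - fl$lifespan_male, 1) else 0
    F_lag <- if (t > fl$lifespan_female)
      deSolve::lagvalue(t - fl$lifespan_female, 2) else 0
    m <- max(y[1] - M_lag, 0)
    f <- max(y[2] - F_lag, 0)
    tot <- m + f
    V <- po$search_rate * tot / (1 + po$search_rate * po$handling_time * tot)
    if (tot > 0) {
      sm <- (m / tot)^po$pref_male
      sf <- (f / tot)^po$pref_female
    } else {
      sm <- 1; sf <- 1
    }
    r1 <- V * (1 - sm) * y[3]
    r2 <- V * sf * y[4]
    r3 <- V * sf * y[5]
    tmv <- V * (1 - sf)
    g <- if (f > sc$accrual_guard) 1 / f else 0
    list(c(dM, dF,
           tmv * (y[4] + y[5] + y[6]) - r1,
           r1 - tmv * y[4] - r2,
           r2 - tmv * y[5] - r3,
           r3 - tmv * y[6],
           r1 * g, r2 * g, r3 * g))
  }
  times <- seq(0, sc$horizon, by = sc$grid_step)
  y0 <- c(0, 0, 0, 0, 0, n_pollinators(sc), 0, 0, 0)
  out <- deSolve::dede(y = y0, times = times, func = rhs, parms = NULL,
                       rtol = 1e-8, atol = 1e-6)
  oracle_daily_yield(out[, 1], out[, 8:10], sc)
}

# Partial rank correlation from inversion of the full rank-correlation
# matrix, the textbook definition.
prcc_oracle <- function(X, y) {
  R <- cor(cbind(apply(X, 2, rank), rank(y)))
  P <- solve(R)
  k <- ncol(X)
  vapply(seq_len(k), function(j)
    -P[j, k + 1] / sqrt(P[j, j] * P[k + 1, k + 1]), numeric(1))
}
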