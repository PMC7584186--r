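# One default-precision baseline simulation shared by several blocks.
baseline_sim <- simulate_scenario(scenario())

test_that("fruit-set probability composes per-visit chances", {
  fs <- fruitset_params()
  expect_equal(fruit_set_probability(0, 0, 0, fs), 0)
  expect_equal(fruit_set_probability(1, 0, 0, fs), 0.66)
  expect_equal(fruit_set_probability(1, 1, 1, fs),
               1 - 0.34 * 0.45 * 0.78)
  expect_equal(fruit_set_probability(1, 1, 1, fs), 0.88066)
  # invariant under permuting (visit, probability) channel pairs
  fs_perm <- fruitset_params(p1 = 0.22, p2 = 0.66, p3 = 0.55)
  expect_equal(fruit_set_probability(2.5, 0.7, 1.2, fs),
               fruit_set_probability(1.2, 2.5, 0.7, fs_perm))
  # nondecreasing in each exposure
  v <- seq(0, 10, by = 0.5)
  expect_true(all(diff(fruit_set_probability(v, 1, 1, fs)) > 0))
  expect_true(all(fruit_set_probability(v, v, v, fs) <= 1))
  expect_error(fruitset_params(p1 = 1.2), "probability")
  expect_error(fruit_set_probability(-1, 0, 0, fs), ">= 0")
})

test_that("per-flower accrual divides by open females above the guard", {
  expect_equal(per_flower_accrual(1000, 2000), 0.5)
  expect_equal(per_flower_accrual(1000, 1e-9), 0)
  expect_equal(per_flower_accrual(0, 5000), 0)
  expect_error(per_flower_accrual(-1, 10), ">= 0")
  # cumulative accrual: trapezoid of rate/f on the output grid reproduces
  # the integrated A1 to high accuracy
  tr <- baseline_sim$trajectory
  pp <- baseline_sim$scenario$pollinators
  r1 <- mapply(function(m, f, p1)
    deposit_visit_rates(c(p1, 0, 0, 0), m, f, pp)[["type1"]],
    tr$m, tr$f, tr$high_load)
  a1_rate <- per_flower_accrual(r1, tr$f)
  n <- nrow(tr)
  trapz <- cumsum(c(0, (a1_rate[-1] + a1_rate[-n]) / 2 * diff(tr$time)))
  # compare accrual gained across the main bloom (the initial loading-up
  # transient is below the output grid's resolution)
  gain <- function(x) x[tr$time == 15] - x[tr$time == 5]
  expect_equal(gain(trapz), gain(tr$A1), tolerance = 1e-3)
})

test_that("no pollinators means no yield", {
  sc <- fast_controls(scenario(pollinators = pollinator_params(density = 0)))
  sim <- simulate_scenario(sc)
  expect_equal(sim$total_yield, 0)
  expect_equal(sim$fruit_set, 0)
})

test_that("pollinator count is conserved along the baseline trajectory", {
  tr <- baseline_sim$trajectory
  total <- tr$high_load + tr$mid_load + tr$low_load + tr$no_load
  expect_lt(max(abs(total - 3600)) / 3600, 1e-6)
  expect_true(all(tr[c("high_load", "mid_load", "low_load", "no_load")] >
                    -1e-6 * 3600))
})

test_that("visits delivered match visits received by closing cohorts", {
  # field-level integral of each deposit channel vs the cohort bookkeeping
  tr <- baseline_sim$trajectory
  pp <- baseline_sim$scenario$pollinators
  rates <- t(mapply(function(m, f, p1, p2, p3)
    deposit_visit_rates(c(p1, p2, p3, 0), m, f, pp),
    tr$m, tr$f, tr$high_load, tr$mid_load, tr$low_load))
  n <- nrow(tr)
  delivered <- colSums((rates[-1, ] + rates[-n, ]) / 2 * diff(tr$time))
  daily <- baseline_sim$daily
  received <- c(sum(daily$dfc * daily$v1), sum(daily$dfc * daily$v2),
                sum(daily$dfc * daily$v3))
  expect_equal(unname(received / delivered), rep(1, 3), tolerance = 0.005)
})

test_that("adaptive integration agrees with a fixed-step 4th-order oracle", {
  # midpoint closing so both routes share the single-time cohort rule the
  # oracle implements; what differs is the integration method
  sc <- scenario(close_time = "midpoint")
  expect_equal(simulate_scenario(sc)$total_yield, rk4_yield(sc, h = 0.001),
               tolerance = 0.001)
})

test_that("closed-form forcing is equivalent to a literal delay integration", {
  sc <- scenario(close_time = "midpoint")
  expect_equal(simulate_scenario(sc)$total_yield, dde_yield(sc),
               tolerance = 0.001)
})

test_that("yield responds monotonically to bee density and handling time", {
  rhos <- seq(1, 19, by = 2)
  y_rho <- vapply(rhos, function(r) {
    sc <- fast_controls(scenario(pollinators = pollinator_params(density = r)))
    simulate_scenario(sc)$total_yield
  }, numeric(1))
  expect_true(all(diff(y_rho) >= 0))

  betas <- seq(0.0002, 0.009, length.out = 10)
  y_beta <- vapply(betas, function(b) {
    sc <- fast_controls(
      scenario(pollinators = pollinator_params(handling_time = b)))
    simulate_scenario(sc)$total_yield
  }, numeric(1))
  expect_true(all(diff(y_beta) <= 0))
})

test_that("randomized scenarios respect the structural bounds", {
  set.seed(31)
  for (i in 1:200) {
    sc <- random_table_scenario()
    sim <- simulate_scenario(sc)
    expect_gte(sim$fruit_set, 0)
    expect_lte(sim$fruit_set, 1)
    expect_gte(sim$total_yield, 0)
    expect_lte(sim$total_yield, sc$flowers$buds_female)
    expect_true(all(sim$daily$fruit_set >= 0 & sim$daily$fruit_set <= 1))
    expect_true(all(sim$daily$v1 >= 0))
    total <- rowSums(sim$trajectory[c("high_load", "mid_load", "low_load",
                                      "no_load")])
    p0 <- n_pollinators(sc)
    expect_lt(max(abs(total - p0)) / p0, 1e-6)
  }
})

test_that("a horizon that cuts the bloom short is rejected", {
  expect_error(scenario(horizon = 8), "horizon")
  sc <- scenario(horizon = 13)  # valid per the static check, bloom unfinished
  expect_error(simulate_scenario(sc), "still open")
})

test_that("simulation outputs export to CSV/JSON and read back", {
  dir <- withr::local_tempdir()
  paths <- export_simulation(baseline_sim, dir)
  expect_true(all(file.exists(paths)))
  daily <- read.csv(paths[2])
  expect_equal(daily$yield, baseline_sim$daily$yield)
  summ <- jsonlite::read_json(paths[3])
  expect_equal(summ$total_yield, baseline_sim$total_yield)
})
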