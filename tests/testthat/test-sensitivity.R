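test_that("latin hypercube designs are stratified, reproducible, uniform", {
  r <- parameter_ranges()
  d <- lhs_sample(r, 10, seed = 7)
  # exactly one draw in each decile of every parameter's range
  for (j in seq_len(nrow(r))) {
    u <- (d$samples[, j] - r$low[j]) / (r$high[j] - r$low[j])
    expect_equal(sort(floor(u * 10)), 0:9)
  }
  expect_identical(lhs_sample(r, 10, seed = 7)$samples, d$samples)
  expect_false(identical(lhs_sample(r, 10, seed = 8)$samples, d$samples))

  # marginals approach uniformity at the KS rate
  d1k <- lhs_sample(r, 1000, seed = 7)
  ks <- vapply(seq_len(nrow(r)), function(j) {
    u <- sort((d1k$samples[, j] - r$low[j]) / (r$high[j] - r$low[j]))
    max(abs(u - (seq_along(u) - 0.5) / length(u)))
  }, numeric(1))
  expect_gte(sum(ks < 1.36 / sqrt(1000)), 15)

  expect_error(lhs_sample(r, 1, seed = 1), "n >= 2")
  r$high[1] <- r$low[1]
  expect_error(lhs_sample(r, 100, seed = 1), "degenerate")
})

test_that("the raw sampling basis swaps bud composition for raw counts", {
  rr <- parameter_ranges(basis = "raw")
  expect_true(all(c("buds_male", "buds_female") %in% rr$name))
  expect_false(any(c("total_buds", "pct_female") %in% rr$name))
  d <- lhs_sample(rr, 20, seed = 3)
  sc <- scenario_from_draw(d$samples[1, ])
  expect_equal(sc$flowers$buds_male, unname(d$samples[1, "buds_male"]))
})

test_that("PRCC equals the rank-correlation-matrix-inversion oracle", {
  set.seed(41)
  n <- 50
  X <- cbind(a = runif(n), b = runif(n), c = runif(n))
  y <- 2 * X[, "a"] - X[, "b"]^2 + 0.3 * rnorm(n)
  rep <- prcc(X, y)
  expect_equal(rep$prcc, prcc_oracle(X, y), tolerance = 1e-10)
  expect_true(all(abs(rep$prcc) <= 1))
})

test_that("PRCC isolates a monotone driver from noise parameters", {
  set.seed(42)
  n <- 200
  X <- matrix(runif(n * 5), n, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- exp(2 * X[, 1]) + 0.05 * rnorm(n)
  rep <- prcc(X, y)
  expect_gt(rep$prcc[rep$parameter == "x1"], 0.95)
  expect_true(all(abs(rep$prcc[rep$parameter != "x1"]) < 0.2))
  expect_true(rep$significant[rep$parameter == "x1"])
})

test_that("PRCC p-values are calibrated under the null", {
  set.seed(43)
  n_sig <- 0
  reps <- 150
  for (i in seq_len(reps)) {
    X <- matrix(runif(400), 100, 4)
    colnames(X) <- paste0("x", 1:4)
    rep <- prcc(X, runif(100))
    n_sig <- n_sig + sum(rep$significant)
  }
  frac <- n_sig / (4 * reps)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.09)
})

test_that("PRCC is invariant under monotone transforms of the output", {
  set.seed(44)
  X <- matrix(runif(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] - 2 * X[, 2] + 0.2 * rnorm(100)
  expect_equal(prcc(X, y)$prcc, prcc(X, exp(3 * y))$prcc)
  expect_error(prcc(cbind(X, d = rep(1, 100)), y), "constant")
})

test_that("monotonicity screen separates monotone from hump-shaped responses", {
  set.seed(45)
  n <- 400
  X <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  mono <- monotonicity_check(X, X[, "a"], "a")
  expect_true(mono$monotone)
  expect_null(mono$split)

  y <- -(X[, "a"] - 0.5)^2 + 0.01 * rnorm(n)
  hump <- monotonicity_check(X, y, "a")
  expect_false(hump$monotone)
  expect_lt(abs(hump$split - 0.5), 0.15)
})

test_that("a one-row batch at the base values reproduces the base run", {
  base <- fast_controls(scenario())
  draw <- c(total_buds = 1.2e6, pct_female = 0.5, search_rate = 480,
            handling_time = 0.0011,
            pref_male = preference_from_stay(0.957),
            pref_female = preference_from_stay(0.951),
            peak_male = 6, peak_female = 6, spread_male = 2.5,
            spread_female = 2, lifespan_male = 4, lifespan_female = 5,
            density = 6, p1 = 0.66, p2 = 0.55, p3 = 0.22)
  y <- run_batch(matrix(draw, 1, dimnames = list(NULL, names(draw))), base)
  expect_equal(unname(y[1]), simulate_scenario(base)$total_yield)
  expect_equal(nrow(attr(y, "failures")), 0)
})

test_that("bee density shifts batch yields as the density range predicts", {
  base <- fast_controls(scenario())
  r <- parameter_ranges()
  d <- lhs_sample(r, 20, seed = 9)
  lo <- d$samples; lo[, "density"] <- 1
  hi <- d$samples; hi[, "density"] <- 20
  y_lo <- run_batch(lo, base)
  y_hi <- run_batch(hi, base)
  expect_gt(mean(y_hi), mean(y_lo))
  expect_true(all(y_hi >= y_lo))
})

test_that("truncating to the full original range reproduces the full PRCC", {
  base <- fast_controls(scenario())
  r <- parameter_ranges()
  n <- 20
  full_design <- lhs_sample(r, n, seed = 5)
  full <- prcc(full_design, run_batch(full_design, base))
  trunc <- truncated_prcc(
    list(pct_female = c(r$low[r$name == "pct_female"],
                        r$high[r$name == "pct_female"])),
    ranges = r, n = n, seed = 5, base = base)
  expect_equal(trunc$prcc, full$prcc)
  expect_error(truncated_prcc(list(pct_female = c(0.5, 2)), r, n, 5, base),
               "within")
  expect_error(truncated_prcc(list(nope = c(0, 1)), r, n, 5, base),
               "unknown")
})
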