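test_that("cumulative openings agree with quadrature of the Gaussian rate", {
  # frozen spot checks (Gaussian tail/CDF evaluations)
  expect_equal(cumulative_opened(0, 600000, 6, 2.5), 0)
  expect_equal(cumulative_opened(Inf, 600000, 6, 2.5),
               595081.5, tolerance = 1e-5)
  expect_equal(cumulative_opened(6, 600000, 6, 2.5),
               295081.5, tolerance = 1e-5)

  set.seed(11)
  for (i in 1:100) {
    buds <- runif(1, 3e5, 9e5)
    peak <- runif(1, 2, 9)
    spread <- runif(1, 0.5, 5.5)
    t <- runif(1, 0.1, 25)
    expect_equal(cumulative_opened(t, buds, peak, spread),
                 quad_cumulative(t, buds, peak, spread),
                 tolerance = 1e-8)
  }
})

test_that("cumulative openings are nondecreasing, bounded, and additive", {
  t <- seq(0, 30, by = 0.1)
  M <- cumulative_opened(t, 600000, 6, 2.5)
  expect_true(all(diff(M) >= 0))
  expect_true(all(M <= 600000))
  # differences over disjoint intervals add up
  expect_equal((cumulative_opened(8, 6e5, 6, 2.5) -
                  cumulative_opened(4, 6e5, 6, 2.5)) +
                 (cumulative_opened(4, 6e5, 6, 2.5) -
                    cumulative_opened(1, 6e5, 6, 2.5)),
               cumulative_opened(8, 6e5, 6, 2.5) -
                 cumulative_opened(1, 6e5, 6, 2.5))
  expect_error(cumulative_opened(1, 6e5, 6, 0), "spread")
  expect_error(cumulative_opened(1, -5, 6, 2.5), "buds")
})

test_that("open counts subtract one lifespan of openings", {
  expect_equal(open_count(0, 6e5, 6, 2.5, 4), 0)
  # infinite lifespan: nothing ever closes
  t <- seq(0, 20, by = 0.5)
  expect_equal(open_count(t, 6e5, 6, 2.5, Inf),
               cumulative_opened(t, 6e5, 6, 2.5))
  # M(8) - M(4), cross-checked by quadrature over (4, 8]
  expect_equal(open_count(8, 6e5, 6, 2.5, 4),
               quad_cumulative(8, 6e5, 6, 2.5) -
                 quad_cumulative(4, 6e5, 6, 2.5),
               tolerance = 1e-8)
})

test_that("open counts stay within [0, buds] across random parameter draws", {
  set.seed(12)
  t <- seq(0, 40, by = 0.25)
  for (i in 1:100) {
    buds <- runif(1, 3e5, 9e5)
    m <- open_count(t, buds, runif(1, 2, 9), runif(1, 0.5, 5.5),
                    runif(1, 3, 7))
    expect_true(all(m >= 0))
    expect_true(all(m <= buds))
  }
})

test_that("daily female closings tile the cumulative bloom", {
  fl <- flower_params()
  expect_equal(daily_female_closing(0:30,
                                    flower_params(buds_female = 0)),
               rep(0, 31))
  # no flower can close before one lifespan has elapsed
  expect_equal(daily_female_closing(0:3, fl), rep(0, 4))
  # day 10 window, against quadrature
  expect_equal(daily_female_closing(10, fl),
               quad_cumulative(11 - 5, 6e5, 6, 2) -
                 quad_cumulative(10 - 5, 6e5, 6, 2),
               tolerance = 1e-8)
  # telescoping: closings up to day D sum to openings by D - lifespan
  D <- 40
  expect_equal(sum(daily_female_closing(0:(D - 1), fl)),
               cumulative_opened(D - fl$lifespan_female, 6e5, 6, 2))
})

test_that("bloom overlap diagnostics behave at the edges", {
  none <- bloom_overlap(flower_params(buds_male = 0))
  expect_equal(none$integral, 0)

  sym <- flower_params(buds_male = 5e5, buds_female = 5e5,
                       peak_male = 6, peak_female = 6,
                       spread_male = 2, spread_female = 2,
                       lifespan_male = 5, lifespan_female = 5)
  ov <- bloom_overlap(sym, grid_step = 0.05)
  tr <- bloom_trajectory(sym, grid_step = 0.05)
  expect_equal(ov$overlap, tr$m)
  expect_equal(ov$overlap, tr$f)

  # grid refinement changes the integral by < 0.1%
  fl <- flower_params(peak_male = 7, peak_female = 8,
                      spread_male = 1, spread_female = 1,
                      lifespan_male = 5, lifespan_female = 6)
  coarse <- bloom_overlap(fl, grid_step = 0.02)$integral
  fine <- bloom_overlap(fl, grid_step = 0.002)$integral
  expect_lt(abs(coarse - fine) / fine, 0.001)
})

test_that("bloom trajectories carry consistent columns and closings", {
  fl <- flower_params()
  tr <- bloom_trajectory(fl, grid_step = 0.05)
  expect_true(all(tr$m <= tr$M + 1e-9))
  expect_true(all(tr$f <= tr$F + 1e-9))
  expect_true(all(diff(tr$M) >= 0))
  dfc <- attr(tr, "daily_female_closing")
  expect_true(all(dfc >= 0))
  expect_equal(sum(dfc),
               cumulative_opened(length(dfc) - fl$lifespan_female,
                                 fl$buds_female, fl$peak_female,
                                 fl$spread_female))
})
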