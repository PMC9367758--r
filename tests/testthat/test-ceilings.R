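# Ceiling estimation: the CE-FDH step, the CR-FDH line, zone areas and
# accuracy.

test_that("CE-FDH on the diagonal micro-example: steps, area 3, accuracy 100", {
  obs <- nca_observations(c(0, 1, 2), c(0, 1, 2))
  fit <- fit_ce_fdh(obs)

  expect_equal(fit$breakpoints$x, c(0, 1, 2))
  expect_equal(fit$breakpoints$value, c(0, 1, 2))
  expect_equal(ceiling_value(fit, c(0, 0.5, 1, 1.5, 2)), c(0, 0, 1, 1, 2))
  expect_equal(fit$zone_area, 3)
  expect_equal(fit$d, 0.75)
  expect_equal(fit$accuracy, 100)
  expect_equal(fit$peers$x, c(0, 1, 2))
})

test_that("an occupied upper-left corner gives a flat ceiling and zero zone", {
  obs <- nca_observations(c(0, 2), c(2, 0))
  fit <- fit_ce_fdh(obs)
  expect_equal(ceiling_value(fit, c(0, 1, 2)), c(2, 2, 2))
  expect_equal(fit$zone_area, 0)
  expect_equal(fit$d, 0)
  # and CR-FDH is undefined: only one corner point
  expect_error(fit_cr_fdh(obs), "CE-FDH")
})

test_that("CE-FDH accuracy is 100% on arbitrary random datasets", {
  for (seed in 1:25) {
    obs <- random_obs(n = sample(3:60, 1), seed = seed)
    fit <- fit_ce_fdh(obs)
    expect_equal(fit$accuracy, 100)
    # the ceiling zone is empty: no observation strictly above the step
    expect_true(all(obs$y <= ceiling_value(fit, obs$x) + 1e-9))
  }
})

test_that("CR-FDH through collinear corners reproduces the line exactly", {
  obs <- nca_observations(c(0, 1, 2), c(0, 1, 2))
  fit <- fit_cr_fdh(obs)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$zone_area, 2)     # area above y = x in [0,2]^2
  expect_equal(fit$d, 0.5)
  expect_equal(fit$accuracy, 100)
  # residuals at the corners are zero
  expect_equal(ceiling_value(fit, fit$peers$x), fit$peers$y)
})

test_that("CR-FDH accuracy counts points on or below the line; <95% is flagged", {
  # concave corner set: the middle corner sits above the OLS line
  obs <- nca_observations(c(0, 1, 2), c(0, 0.9, 1))
  fit <- fit_cr_fdh(obs)
  expect_equal(fit$accuracy, 100 * 2 / 3, tolerance = 1e-9)
  expect_false(fit$interpretable)    # < 95%: not for interpretation

  # points exactly on the line count as below
  obs2 <- nca_observations(c(0, 1, 2, 1), c(0, 1, 2, 0.5))
  expect_equal(fit_cr_fdh(obs2)$accuracy, 100)
})

test_that("zone areas match fine-grid numerical integration (independent oracle)", {
  for (seed in 1:8) {
    obs <- random_obs(n = sample(5:50, 1), seed = 100 + seed)
    methods <- if (nrow(fit_ce_fdh(obs)$peers) >= 2) c("ce_fdh", "cr_fdh")
               else "ce_fdh"          # CR undefined with an occupied corner
    for (m in methods) {
      fit <- fit_ceiling(obs, method = m)
      oracle <- oracle_zone_area(fit, cells = 2e5)
      expect_equal(fit$zone_area, oracle, tolerance = 1e-3,
                   label = sprintf("%s zone area (seed %d)", m, seed))
    }
  }
})

test_that("ceiling_value inverts known lines and rejects out-of-scope x", {
  # linear ceiling with printed coefficients: y = 0.15 x + 6.27 at x = 10
  obs <- nca_observations(c(0, 10), c(6.27, 7.77))
  fit <- fit_cr_fdh(obs)
  expect_equal(fit$slope, 0.15)
  expect_equal(fit$intercept, 6.27)
  expect_equal(ceiling_value(fit, 10), 7.77)
  expect_error(ceiling_value(fit, 11), "outside the scope")

  # monotone: value at x_min never exceeds value at x_max
  for (seed in 1:5) {
    o <- random_obs(20, seed = 200 + seed)
    for (m in c("ce_fdh", "cr_fdh")) {
      f <- fit_ceiling(o, method = m)
      sc <- f$scope
      expect_lte(ceiling_value(f, sc$x_min), ceiling_value(f, sc$x_max))
    }
  }
})

test_that("adding a dominated point changes neither the step nor its area", {
  for (seed in 1:10) {
    obs <- random_obs(20, seed = 300 + seed)
    fit <- fit_ce_fdh(obs)
    sc <- fit$scope
    # a point strictly below the ceiling, inside scope
    px <- runif(1, sc$x_min, sc$x_max)
    top <- ceiling_value(fit, px)
    if (top <= sc$y_min) next
    py <- runif(1, sc$y_min, top)
    obs2 <- nca_observations(c(obs$x, px), c(obs$y, py))
    fit2 <- fit_ce_fdh(obs2, scope = sc)
    expect_equal(fit2$breakpoints, fit$breakpoints)
    expect_equal(fit2$zone_area, fit$zone_area)
  }
})

test_that("raising the scope top by delta adds exactly delta * width (CE-FDH)", {
  for (seed in 1:5) {
    obs <- random_obs(15, seed = 400 + seed)
    sc <- nca_scope(obs)
    delta <- runif(1, 0.5, 2)
    sc2 <- nca_scope(obs, x_min = sc$x_min, x_max = sc$x_max,
                     y_min = sc$y_min, y_max = sc$y_max + delta)
    a1 <- fit_ce_fdh(obs, sc)$zone_area
    a2 <- fit_ce_fdh(obs, sc2)$zone_area
    expect_equal(a2 - a1, delta * (sc$x_max - sc$x_min))
  }
})

test_that("scope validation: observations outside, degenerate rectangles", {
  obs <- nca_observations(c(0, 1), c(0, 1))
  expect_error(nca_scope(obs, x_max = 0.5), "contain all observations")
  expect_error(nca_scope(x_min = 0, x_max = 0, y_min = 0, y_max = 1),
               "degenerate")
  sc <- nca_scope(x_min = 0, x_max = 0.5, y_min = 0, y_max = 2)
  expect_error(fit_ce_fdh(obs, sc), "outside the scope")
})

test_that("CR-FDH line is clipped to the scope so d stays in [0, 1]", {
  # steep line: unclipped area above it would spill outside the rectangle
  obs <- nca_observations(c(0, 0.1, 1), c(0, 0.9, 1))
  fit <- fit_cr_fdh(obs)
  expect_gte(fit$d, 0)
  expect_lte(fit$d, 1)
  expect_equal(fit$zone_area, oracle_zone_area(fit, cells = 2e5),
               tolerance = 1e-4)
})
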