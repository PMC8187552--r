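test_that("MLD follows the 0.2 degC criterion with linear interpolation", {
  # theta(10 m) = 28, linear 28 -> 26 between 30 and 50 m: crossing of
  # 27.8 degC at 32 m
  cs <- cast("A", "2017-01-01", c(0, 10, 30, 50),
             temperature = c(28, 28, 28, 26), salinity = rep(34.91, 4))
  r <- compute_mld(cs)
  expect_equal(r$mld, 32)
  expect_false(r$mld_not_reached)

  # isothermal: criterion never met, deepest depth + flag
  iso <- cast("A", "2017-01-01", c(0, 10, 100, 200),
              temperature = rep(25, 4), salinity = rep(34.91, 4))
  r <- compute_mld(iso)
  expect_equal(r$mld, 200)
  expect_true(r$mld_not_reached)

  # exact 0.2 degC drop at a sampled depth: that depth, no flag
  cs <- cast("A", "2017-01-01", c(0, 10, 50, 100),
             temperature = c(27, 27, 26.8, 25), salinity = rep(34.91, 4))
  r <- compute_mld(cs)
  expect_equal(r$mld, 50)
  expect_false(r$mld_not_reached)

  # invariant to adding redundant interpolated levels
  cs2 <- cast("A", "2017-01-01", c(0, 10, 30, 40, 50),
              temperature = c(28, 28, 28, 27, 26), salinity = rep(34.91, 5))
  expect_equal(compute_mld(cs2)$mld, 32)

  shallow <- cast("A", "2017-01-01", c(0, 5), temperature = c(28, 28),
                  salinity = c(34.91, 34.91))
  expect_error(compute_mld(shallow), "10 m")
})

test_that("EZD inverts exponential PAR decay via log-linear interpolation", {
  z <- c(0, 10, 25, 50, 75, 100, 125, 150, 200)
  cs <- make_test_cast(par = 2000 * exp(-0.046 * z))
  r <- compute_ezd(cs)
  expect_equal(r$ezd, log(100) / 0.046, tolerance = 1e-9)
  expect_false(r$ezd_not_reached)

  # constant PAR never reaches 1 %
  r <- compute_ezd(make_test_cast(par = rep(500, 9)))
  expect_true(r$ezd_not_reached)
  expect_equal(r$ezd, 200)

  # PAR exactly 1 % at a sampled depth
  par <- 1000 * 0.1^(z / 50)   # 1 % at exactly 100 m
  r <- compute_ezd(make_test_cast(par = par))
  expect_equal(r$ezd, 100, tolerance = 1e-12)

  bad <- make_test_cast(par = c(0, rep(1, 8)))
  expect_error(compute_ezd(bad), "surface PAR")
})

test_that("below-detection substitution replaces N+N and PO4 and is idempotent", {
  cs <- make_test_cast(conc = list(
    nn = c(1, 2.9, 10, 50, 100, 500, 1000, 2000, 3000) * 1e-6,
    po4 = c(2, 1, 3, 10, 20, 50, 100, 150, 250) * 1e-6,
    dop = rep(2e-6, 9)))
  out <- substitute_below_detection(cs)
  expect_equal(out$conc$nn[1:2] / 1e-6, c(5, 5))      # below 3 nM limit -> 5
  expect_equal(out$conc$nn[3] / 1e-6, 10)             # above limit untouched
  expect_equal(out$conc$po4[1:2] / 1e-6, c(3, 3))     # below 3 nM limit -> 3
  expect_equal(out$conc$po4[3] / 1e-6, 3)             # at the limit untouched
  expect_equal(out$conc$dop, cs$conc$dop)             # unconfigured untouched
  expect_equal(attr(out, "n_substituted"), c(nn = 2L, po4 = 2L))

  again <- substitute_below_detection(out)
  expect_equal(again$conc, out$conc)
  expect_equal(sum(attr(again, "n_substituted")), 0L)
})

test_that("salinity normalization scales by reference over observed salinity", {
  expect_equal(normalize_salinity(2.0, 34.91), 2.0)
  expect_equal(normalize_salinity(7.3, 34.91 / 2), 14.6)
  expect_equal(normalize_salinity(2.02, 35.26), 2.02 * 34.91 / 35.26)
  expect_equal(normalize_salinity(2.02, 35.26), 2.0000, tolerance = 1e-4)
  # linear in x
  expect_equal(normalize_salinity(10 * 2.02, 35.26),
               10 * normalize_salinity(2.02, 35.26))
  expect_error(normalize_salinity(1, 0), "> 0")
})

test_that("buoyancy frequency matches the finite-difference hand value", {
  # two-level density 1024 at 50 m, 1025 at 150 m on the 5-m grid
  grid <- seq(50, 150, by = 5)
  rho <- approx(c(50, 150), c(1024, 1025), xout = grid)$y
  nsq <- n_sq_from_density(grid, rho)
  expect_equal(nsq, rep(9.81 / 1025 * 0.01, length(grid)), tolerance = 1e-9)
  expect_equal(nsq[1], 9.57e-5, tolerance = 1e-3)

  # uniform T and S: N^2 = 0 everywhere
  uni <- make_test_cast(temperature = rep(25, 9), salinity = rep(34.91, 9))
  expect_true(all(abs(buoyancy_frequency_sq(uni)$n_sq) < 1e-12))

  # temperature decreasing with depth (density increasing): N^2 > 0
  strat <- make_test_cast()
  expect_true(all(buoyancy_frequency_sq(strat)$n_sq > 0))
})

test_that("trapezoidal inventories match the quadrature oracle and add over layers", {
  z <- c(0, 10, 25, 50, 75, 100, 125, 150, 200)
  # constant and linear-ramp closed forms
  expect_equal(depth_integrate(z, rep(0.1, 9), 0, 100), 10)
  expect_equal(depth_integrate(z, 0.2 * z / 100, 0, 100), 10)

  set.seed(11)
  for (i in 1:10) {
    v <- runif(9, 0, 2)
    got <- depth_integrate(z, v, 0, 200)
    expect_equal(got, quadrature_inventory(z, v, 0, 200),
                 tolerance = 1e-12)
    # additivity over contiguous layers and interior endpoints
    expect_equal(depth_integrate(z, v, 0, 100) + depth_integrate(z, v, 100, 200),
                 got, tolerance = 1e-12)
    expect_equal(depth_integrate(z, v, 30, 130),
                 quadrature_inventory(z, v, 30, 130), tolerance = 1e-12)
    expect_gte(got, 0)
  }

  # nearest-sample extension outside the sampled range
  expect_equal(depth_integrate(c(10, 20), c(1, 1), 0, 30), 30)
  expect_error(depth_integrate(numeric(0), numeric(0), 0, 10), "empty")
  expect_error(depth_integrate(z, rep(1, 9), 100, 100), "z0 < z1")
})

test_that("regime inventory difference propagates CIs through the difference", {
  d <- regime_inventory_difference(c(10, 12, 8, 8), c("c", "c", "w", "w"),
                                   "c", "w")
  expect_equal(d$m, 3)
  expect_equal(d$e, sqrt(mean_ci(c(10, 12))$e^2 + mean_ci(c(8, 8))$e^2),
               tolerance = 1e-12)

  same <- regime_inventory_difference(c(5, 6, 5, 6), c("a", "a", "b", "b"),
                                      "a", "b")
  expect_equal(same$m, 0)
  expect_gt(same$e, 0)

  expect_error(
    regime_inventory_difference(c(1, 2, 3), c("a", "a", "b"), "a", "b"),
    ">= 2 casts")
})
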