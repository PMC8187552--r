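test_that("SST regimes are half-open bins with lower edge inclusive", {
  expect_equal(as.character(classify_sst_regime(23.9)), "SST<24")
  expect_equal(as.character(classify_sst_regime(24.0)), "24-26")
  expect_equal(as.character(classify_sst_regime(26.0)), "26-28")
  expect_equal(as.character(classify_sst_regime(28.0)), "SST>28")
  expect_equal(as.character(classify_sst_regime(30.51)), "SST>28")
  expect_equal(as.character(classify_sst_regime(20.21)), "SST<24")
  expect_error(classify_sst_regime(NaN), "non-finite")
})

test_that("regime days convert month counts at 365/12 and conserve the year", {
  all_warm <- regime_days(rep(30, 12))
  expect_equal(unname(all_warm$days), c(0, 0, 0, 365))

  # 4, 3, 2, 3 months across the regimes
  sst <- c(rep(22, 4), rep(25, 3), rep(27, 2), rep(29, 3))
  clim <- regime_days(sst)
  expect_equal(unname(clim$months), c(4, 3, 2, 3))
  expect_equal(unname(clim$days), c(4, 3, 2, 3) * 365 / 12, tolerance = 1e-12)
  expect_equal(unname(round(clim$days, 2)), c(121.67, 91.25, 60.83, 91.25))

  set.seed(3)
  for (i in 1:25) {
    expect_equal(sum(regime_days(runif(12, 15, 35))$days), 365,
                 tolerance = 1e-9)
  }
  expect_error(regime_days(1:5), "12 monthly")
})

test_that("annual upward influx scales regime fluxes by regime days", {
  clim <- regime_days(rep(30, 12))   # all 365 days in the warm regime
  one <- annual_upward_influx(list("SST>28" = uncertain(1e-6, 0)), clim)
  expect_equal(one$m, 3.65e-4)
  expect_equal(one$e, 0)

  zero <- annual_upward_influx(
    list("SST>28" = uncertain(0, 0)), clim)
  expect_equal(zero$m, 0)

  # regime with days but no data contributes zero with a warning
  clim2 <- regime_days(c(rep(22, 6), rep(30, 6)))
  expect_warning(
    got <- annual_upward_influx(list("SST<24" = uncertain(2e-6, 1e-7)),
                                clim2),
    "no flux data")
  expect_equal(got$m, 2e-6 * 365 / 2)

  expect_error(suppressWarnings(annual_upward_influx(list(), clim)),
               "no regime")
})

test_that("atmospheric influxes integrate the forcing rates over the year", {
  forcing <- atmospheric_forcing()
  clim <- regime_days(c(rep(22, 5), rep(25, 2), rep(27, 2), rep(29, 3)))

  p <- annual_atmospheric_influx("P", forcing)
  expect_equal(p$m, 8.4e-8 * 365, tolerance = 1e-12)
  expect_equal(p$m, 3.066e-5, tolerance = 1e-12)
  expect_equal(p$e, 5.4e-8 * 365, tolerance = 1e-12)

  n <- annual_atmospheric_influx("N", forcing)
  expect_equal(n$m, (2.2e-4 + 2.7e-5) * 365, tolerance = 1e-12)
  expect_equal(n$m, 9.02e-2, tolerance = 1e-3)
  expect_equal(n$e, 365 * sqrt(6.4e-5^2 + 5.7e-6^2), tolerance = 1e-12)

  co2 <- annual_atmospheric_influx("C", forcing, clim)
  expect_equal(co2$m,
               sum(forcing$co2_flux_monthly * c(5, 2, 2, 3)),
               tolerance = 1e-12)

  zero <- atmospheric_forcing(
    co2_flux_monthly = c("SST<24" = 0, "24-26" = 0, "26-28" = 0,
                         "SST>28" = 0),
    n2_fixation = uncertain(0, 0), n_deposition = uncertain(0, 0),
    p_deposition = uncertain(0, 0))
  expect_equal(annual_atmospheric_influx("N", zero)$m, 0)
  expect_equal(annual_atmospheric_influx("P", zero)$m, 0)

  expect_error(atmospheric_forcing(n2_fixation = uncertain(-1e-5, 0)),
               ">= 0")
})

test_that("NCP closure sums influxes with quadrature CIs", {
  # reconstructs the printed P requirement from its parts
  ncp_p <- ncp_requirement(uncertain(2.89e-4, 3e-5), uncertain(3.066e-5, 2e-5))
  expect_equal(signif(ncp_p$m, 2), 3.2e-4)

  a <- uncertain(0.4, 0)
  expect_equal(ncp_requirement(a, uncertain(0, 0)), a, ignore_attr = TRUE)
  expect_equal(ncp_requirement(uncertain(3, 4), uncertain(4, 3))$e, 5)
})

test_that("stoichiometric ratios normalize to P = 1 and are scale invariant", {
  r <- suppressMessages(stoichiometric_ratio(
    uncertain(2, 0.2), uncertain(2, 0.2), uncertain(1, 0.1)))
  expect_equal(r$c$m, 2)
  expect_equal(r$n$m, 2)
  expect_equal(r$p, 1)

  r <- suppressMessages(stoichiometric_ratio(
    uncertain(7.5e-1, 0), uncertain(9.5e-2, 0), uncertain(3.2e-4, 0)))
  expect_equal(r$c$m, 7.5e-1 / 3.2e-4, tolerance = 1e-12)
  expect_equal(round(r$c$m), 2344)
  expect_equal(round(r$n$m), 297)

  k <- 1e3
  rk <- suppressMessages(stoichiometric_ratio(
    uncertain(k * 7.5e-1, 0), uncertain(k * 9.5e-2, 0),
    uncertain(k * 3.2e-4, 0)))
  expect_equal(rk$c$m, r$c$m, tolerance = 1e-12)
  expect_equal(rk$n$m, r$n$m, tolerance = 1e-12)

  expect_error(stoichiometric_ratio(uncertain(1, 0), uncertain(1, 0),
                                    uncertain(0, 0)), "> 0")
})

test_that("microbial demand divides NCP-C by the stoichiometry ranges", {
  md <- microbial_demand(7.5e-1)
  expect_equal(md$md_n, c(7.5e-1 / 11, 7.5e-1 / 6), tolerance = 1e-12)
  expect_equal(md$md_n_2sf, c(6.8e-2, 1.2e-1))
  expect_equal(md$md_p_2sf, c(3.1e-3, 7.0e-3))

  # degenerate range collapses to a point
  pt <- microbial_demand(7.5e-1, stoichiometry_range(cn = c(10, 10)))
  expect_equal(pt$md_n, rep(7.5e-2, 2))

  # monotone in NCP-C
  lo <- microbial_demand(0.5); hi <- microbial_demand(0.9)
  expect_true(all(hi$md_n > lo$md_n) && all(hi$md_p > lo$md_p))
  expect_error(microbial_demand(0), "> 0")
  expect_error(stoichiometry_range(cn = c(11, 6)), "ordered")
})

test_that("recycling factors are MD/NCP with ordered bounds", {
  rf <- recycling_factor(c(3.1e-3, 7.0e-3), 3.2e-4)
  expect_equal(rf$rf_2sf, c(9.7, 22))

  rf_n <- recycling_factor(c(6.8e-2, 1.2e-1), 9.5e-2)
  expect_equal(rf_n$rf_2sf, c(0.72, 1.3))

  expect_equal(recycling_factor(c(0.4, 0.4), 0.4)$rf, c(1, 1))
  expect_true(all(diff(rf$rf) >= 0))
  expect_error(recycling_factor(c(1, 2), 0), "> 0")
})

test_that("compute_budget closes every element budget exactly", {
  clim <- regime_days(c(rep(22, 5), rep(25, 2), rep(27, 2), rep(29, 3)))
  regime_flux <- list(
    dic = list("SST<24" = uncertain(2.5e-4, 5e-5),
               "24-26" = uncertain(2.0e-4, 4e-5),
               "26-28" = uncertain(1.5e-4, 4e-5),
               "SST>28" = uncertain(0.8e-4, 3e-5)),
    nn = list("SST<24" = uncertain(1.8e-5, 4e-6),
              "24-26" = uncertain(1.5e-5, 4e-6),
              "26-28" = uncertain(1.1e-5, 3e-6),
              "SST>28" = uncertain(0.6e-5, 2e-6)),
    po4 = list("SST<24" = uncertain(1.1e-6, 2e-7),
               "24-26" = uncertain(0.9e-6, 2e-7),
               "26-28" = uncertain(0.7e-6, 2e-7),
               "SST>28" = uncertain(0.4e-6, 1e-7)))
  b <- suppressMessages(compute_budget(regime_flux, clim))
  for (el in c("C", "N", "P")) {
    expect_identical(b$ncp[[el]]$m, b$fup[[el]]$m + b$fat[[el]]$m)
  }
  expect_equal(b$ncp_ratio$p, 1)
  expect_true(all(b$rf_p$rf > 0))
})
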