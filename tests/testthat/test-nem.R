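test_that("drawdown rate converts delta_C with the 13-day flushing time", {
  # published extremes: DIC -72.8 -> 5.6; nitrate -7.7 -> 0.6 umol/kg/d
  expect_equal(drawdown_rate(-72.8, 13), 5.6)
  expect_equal(drawdown_rate(-7.7, 13), 7.7 / 13)
  expect_equal(round(drawdown_rate(-7.7, 13), 1), 0.6)
  expect_equal(drawdown_rate(0, 13), 0)
  # sinks (negative delta_C) give positive rates
  expect_gt(drawdown_rate(-1, 13), 0)
  expect_lt(drawdown_rate(1, 13), 0)
  # homogeneity: halving FT doubles the rate
  expect_equal(drawdown_rate(-4.2, 6.5), 2 * drawdown_rate(-4.2, 13))
  expect_error(drawdown_rate(NaN, 13), "non-finite")
  expect_error(flushing_spec(ft_days = 0))
})

test_that("LOICZ flushing time follows the salt balance and its limits", {
  # V (S_oc - S_fj)/S_oc / Q_fw: 2e10 * (0.35/35) / 100 = 2e6 s = 23.15 d
  expect_equal(loicz_flushing_time(2e10, 100, 35, 34.65),
               2e10 * (0.35 / 35) / 100 / 86400, tolerance = 1e-12)
  expect_equal(round(loicz_flushing_time(2e10, 100, 35, 34.65), 2), 23.15)
  # pure freshwater limit: FT = V/Q_fw
  expect_equal(loicz_flushing_time(2e10, 100, 35, 0), 2e10 / 100 / 86400)
  # FT -> 0 as s_fjord -> s_ocean
  expect_lt(loicz_flushing_time(2e10, 100, 35, 34.99999), 1e-3 * 2e10 / 100 / 86400)
  expect_error(loicz_flushing_time(2e10, 100, 35, 35), "degenerate")
  # monotonic in volume and salinity contrast, decreasing in freshwater flow
  expect_gt(loicz_flushing_time(3e10, 100, 35, 34.65),
            loicz_flushing_time(2e10, 100, 35, 34.65))
  expect_gt(loicz_flushing_time(2e10, 100, 34.65 + 0.5, 34.65),
            loicz_flushing_time(2e10, 100, 34.65 + 0.35, 34.65))
  expect_lt(loicz_flushing_time(2e10, 200, 35, 34.65),
            loicz_flushing_time(2e10, 100, 35, 34.65))
  # flushing_spec resolves the loicz method to days
  fs <- flushing_spec(method = "loicz", volume = 2e10, q_freshwater = 100,
                      s_ocean = 35, s_fjord = 34.65)
  expect_equal(fs$ft_days, loicz_flushing_time(2e10, 100, 35, 34.65))
})

test_that("depth integration and areal upscaling reproduce published magnitudes", {
  # 5.6 umol C/kg/d over 100 m at 1000 kg/m3 -> 0.56 mol, 6.7 g C/m2/d
  v <- integrate_drawdown(5.6, depth = 100, density = 1000, tracer = "dic")
  expect_equal(v$mol_m2_d, 0.56, tolerance = 1e-12)
  expect_equal(round(v$g_m2_d, 1), 6.7)
  # 7.7/13 umol N/kg/d -> 0.06 mol N/m2/d
  v <- integrate_drawdown(drawdown_rate(-7.7, 13), tracer = "nitrate_nitrite")
  expect_equal(round(v$mol_m2_d, 2), 0.06)
  expect_equal(integrate_drawdown(0, tracer = "dic")$g_m2_d, 0)

  # tonnage: published 30-192 t N/d from the g-range extremes
  expect_equal(round(upscale_areal(0.8295, 231.5)), 192)
  expect_equal(round(upscale_areal(0.1293, 231.5)), 30)
  expect_equal(upscale_areal(0), 0)
  expect_error(integrate_drawdown(1, tracer = "mystery"), "molar mass")
})

test_that("the full chain is linear in delta_C and zero maps to zero", {
  chain <- function(dc) {
    upscale_areal(integrate_drawdown(drawdown_rate(dc, 13),
                                     tracer = "nitrate_nitrite")$g_m2_d)
  }
  expect_equal(chain(0), 0)
  dc <- c(-7.7, -1.2, -4.2)
  expect_equal(chain(2 * dc), 2 * chain(dc), tolerance = 1e-12)
  expect_equal(chain(dc[1] + dc[2]), chain(dc[1]) + chain(dc[2]),
               tolerance = 1e-12)
})

test_that("steady-state box model: sources_sinks/FT recovers the uptake rate", {
  # independent oracle: Euler-integrate dC/dt = Q (C_sea - C)/V - r to
  # equilibrium, then push the equilibrium deficit through drawdown_rate
  V <- 2e10; Q <- V / (13 * 86400)  # FT = 13 d
  C_sea <- 11; r <- 0.4             # umol/kg/d uptake
  C <- C_sea; dt <- 0.01            # days
  for (i in seq_len(200 / dt)) C <- C + dt * ((C_sea - C) / 13 - r)
  delta_C <- C - C_sea              # observed minus conservative
  expect_equal(drawdown_rate(delta_C, 13), r, tolerance = 0.02 * r)
})

test_that("C:N uptake ratio averages matched year/pair rate ratios", {
  mk <- function(year, pair, tracer, rate) {
    data.frame(year = year, pair = pair, tracer = tracer, rate = rate)
  }
  nem <- rbind(mk(2015, "AWs_vs_SW", "dic", 6.6 * 0.5),
               mk(2015, "AWs_vs_SW", "nitrate_nitrite", 0.5))
  expect_equal(cn_uptake_ratio(nem)$mean_ratio, 6.6)

  nem <- rbind(mk(2015, "AWs_vs_SW", "dic", 6), mk(2015, "AWs_vs_SW", "nitrate_nitrite", 1),
               mk(2016, "AWs_vs_SW", "dic", 8), mk(2016, "AWs_vs_SW", "nitrate_nitrite", 1))
  expect_equal(cn_uptake_ratio(nem)$mean_ratio, 7.0)

  # exclusions drop a (year, pair); negative-rate pairs never enter
  nem <- rbind(nem,
               mk(2020, "AWs_vs_SW", "dic", 100), mk(2020, "AWs_vs_SW", "nitrate_nitrite", 1),
               mk(2021, "AWs_vs_SW", "dic", -1), mk(2021, "AWs_vs_SW", "nitrate_nitrite", 1))
  out <- cn_uptake_ratio(nem, exclusions = data.frame(year = 2020,
                                                      pair = "AWs_vs_SW"))
  expect_equal(out$mean_ratio, 7.0)
  expect_equal(out$n, 2)
  expect_error(cn_uptake_ratio(nem[nem$tracer == "dic", ]), "insufficient")

  # noisy synthetic estimates around a true ratio of 7
  set.seed(21)
  n_rates <- runif(12, 0.2, 0.6)
  noise <- rnorm(12, 0, 0.05)
  nem <- rbind(
    data.frame(year = rep(2011:2022), pair = "AWs_vs_SW", tracer = "dic",
               rate = 7 * n_rates * (1 + noise)),
    data.frame(year = rep(2011:2022), pair = "AWs_vs_SW",
               tracer = "nitrate_nitrite", rate = n_rates))
  expect_lt(abs(cn_uptake_ratio(nem)$mean_ratio - 7), 0.2)
})

test_that("nem_table applies the chain per row and keeps the NEM pairs only", {
  ss <- kongsfjorden_sources_sinks()
  nem <- nem_table(ss)
  expect_s3_class(nem, "nem_table")
  expect_false(any(nem$pair == "AWs_vs_AWf"))
  expect_equal(nem$rate, -nem$delta_C / 13)
  expect_equal(nem$integrated_mol, nem$rate * 100 * 1000 * 1e-6)
  i <- which(nem$tracer == "dic")
  expect_equal(nem$integrated_g[i], nem$integrated_mol[i] * 12.011)
  # absent delta_C propagates as absent, never zero
  expect_equal(sum(is.na(nem$rate)), sum(is.na(nem$delta_C)))
  # doubling FT halves every rate
  nem2 <- nem_table(ss, ft = 26)
  expect_equal(nem2$rate, nem$rate / 2)
})
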