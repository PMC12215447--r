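test_that("atmospheric deposition converts precip x concentration to t N/d", {
  p <- data.frame(start = as.Date("2020-07-01"), end = as.Date("2020-07-08"),
                  precip_mm = 10, conc_mg_l = 0.2)
  # 2 mg N/m2 over 7 d, upscaled to 231.5 km2
  expect_equal(atmospheric_deposition(p, 231.5)$value,
               (10 * 0.2 / 7) * 231.5e6 / 1e9, tolerance = 1e-12)
  expect_equal(round(atmospheric_deposition(p, 231.5)$value, 3), 0.066)

  # zero precipitation -> 0
  p0 <- p; p0$precip_mm <- 0
  expect_equal(atmospheric_deposition(p0, 231.5)$value, 0)

  # two identical back-to-back periods -> same daily rate
  p2 <- rbind(p, data.frame(start = as.Date("2020-07-08"),
                            end = as.Date("2020-07-15"),
                            precip_mm = 10, conc_mg_l = 0.2))
  expect_equal(atmospheric_deposition(p2, 231.5)$value,
               atmospheric_deposition(p, 231.5)$value, tolerance = 1e-12)

  # overlap warns and uses the union span
  pov <- rbind(p, p)
  expect_warning(out <- atmospheric_deposition(pov, 231.5), "overlap")
  expect_equal(out$value, 2 * atmospheric_deposition(p, 231.5)$value,
               tolerance = 1e-12)
})

test_that("riverine flux is runoff times concentration times molar mass", {
  # 1e6 m3/d at 2 uM: 2000 mol N/d x 14.007 g = 0.028 t/d
  expect_equal(riverine_flux(1e6, 1, 2.0)$value, 2000 * 14.007 / 1e6,
               tolerance = 1e-12)
  expect_equal(round(riverine_flux(1e6, 1, 2.0)$value, 3), 0.028)
  expect_equal(riverine_flux(1e6, 1, 0)$value, 0)
  # doubling both runoff and span leaves the daily flux unchanged
  expect_equal(riverine_flux(2e6, 2, 2.0)$value, riverine_flux(1e6, 1, 2.0)$value)
  expect_error(riverine_flux(-1, 1, 2.0), "negative runoff")

  # unit audit via an independent path: umol/L -> g/L -> L/d
  g_per_L <- 2.0 * 1e-6 * 14.007
  L_per_d <- 1e6 * 1000
  expect_equal(riverine_flux(1e6, 1, 2.0)$value, g_per_L * L_per_d / 1e6,
               tolerance = 1e-9)
})

test_that("ocean exchange flux follows the transport sign", {
  # 10000 m3/s at 5 uM DIN: 4.32e6 mol/d x 14.007 g = 60.5 t/d
  expect_equal(ocean_exchange_flux(10000, 5)$value,
               10000 * 86400 * 5e-3 * 14.007 * 1e-6, tolerance = 1e-12)
  expect_equal(round(ocean_exchange_flux(10000, 5)$value, 1), 60.5)
  expect_equal(ocean_exchange_flux(0, 5)$value, 0)
  expect_equal(ocean_exchange_flux(-10000, 5)$value,
               -ocean_exchange_flux(10000, 5)$value)
})

test_that("flux constructors are linear in concentration and volume", {
  p <- data.frame(start = as.Date("2020-07-01"), end = as.Date("2020-07-08"),
                  precip_mm = 10, conc_mg_l = 0.2)
  for (k in c(0.5, 2, 3)) {
    pk <- p; pk$conc_mg_l <- k * p$conc_mg_l
    expect_equal(atmospheric_deposition(pk, 231.5)$value,
                 k * atmospheric_deposition(p, 231.5)$value, tolerance = 1e-12)
    expect_equal(riverine_flux(k * 1e6, 1, 2.0)$value,
                 k * riverine_flux(1e6, 1, 2.0)$value, tolerance = 1e-12)
    expect_equal(ocean_exchange_flux(10000, k * 5)$value,
                 k * ocean_exchange_flux(10000, 5)$value, tolerance = 1e-12)
  }
})

test_that("internal balance sums signed entries outside excluded categories", {
  led <- flux_ledger(
    flux_entry("river", "riverine", 1.0),
    flux_entry("denitrification", "internal_transformation", -3.0),
    flux_entry("birds", "biological", -0.13),
    flux_entry("DIN exchange", "ocean_exchange", 250, range_lo = 80,
               range_hi = 500))
  expect_equal(internal_balance(led), -2.13, tolerance = 1e-12)
  # permutation-invariant and additive over concatenation
  expect_equal(internal_balance(led[sample(nrow(led)), ]), -2.13,
               tolerance = 1e-12)
  both <- rbind(led, led)
  expect_equal(internal_balance(both), 2 * internal_balance(led),
               tolerance = 1e-12)
  expect_warning(z <- internal_balance(led, exclude = unique(led$category)),
                 "excluded")
  expect_equal(z, 0)
  expect_warning(internal_balance(led[0, ]), "empty")
  expect_error(flux_entry("x", "riverine", 5, range_lo = 1, range_hi = 2),
               "bracket")
})

test_that("budget report renders ranges, signs and subtotals deterministically", {
  led <- flux_ledger(
    flux_entry("DIN exchange", "ocean_exchange", 250, range_lo = 80,
               range_hi = 500),
    flux_entry("birds", "biological", -0.13),
    flux_entry("river", "riverine", 1.0))
  lines <- budget_report(led, file = NULL)
  expect_match(lines[1], "^name")
  expect_true(any(grepl("80 - 500", lines)))
  expect_true(any(grepl("-0\\.130", lines)))
  expect_true(any(grepl("internal balance", lines)))
  # deterministic ordering: same report after shuffling entries
  expect_identical(budget_report(led[c(3, 1, 2), ], file = NULL), lines)
  # empty ledger -> header only
  expect_length(suppressWarnings(budget_report(flux_ledger(), file = NULL)), 1)
})

test_that("budget operations recover the generator's truth fluxes", {
  inp <- generate_budget_inputs(scenario_paper_like(seed = 13))
  dep <- atmospheric_deposition(inp$deposition, 231.5)
  expect_equal(dep$value, inp$truth$atmospheric, tolerance = 1e-9)
  riv <- riverine_flux(sum(inp$runoff$m3_d), nrow(inp$runoff), 2.0)
  expect_equal(riv$value, inp$truth$riverine, tolerance = 1e-9)
  oce <- ocean_exchange_flux(mean(inp$transport$m3_s), 5.0)
  expect_equal(oce$value, inp$truth$ocean_exchange, tolerance = 1e-9)

  # ledger assembled from these recovers the truth balance exactly
  led <- flux_ledger(dep, riv, oce)
  expect_equal(internal_balance(led),
               inp$truth$atmospheric + inp$truth$riverine, tolerance = 1e-9)
})
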