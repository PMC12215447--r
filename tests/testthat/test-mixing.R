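test_that("conservative concentration interpolates between endmembers", {
  m <- endmember(35.0, 12.0, "nitrate_nitrite")
  f <- endmember(0, 2.0, "nitrate_nitrite")
  # endpoint identities
  expect_equal(conservative_concentration(35.0, m, f), 12.0)
  expect_equal(conservative_concentration(0, m, f), 2.0)
  # hand substitution: 2 + 33*10/35
  expect_equal(conservative_concentration(33.0, m, f), 2 + 33 * 10 / 35,
               tolerance = 1e-12)
  expect_equal(round(conservative_concentration(33.0, m, f), 4), 11.4286)

  expect_error(conservative_concentration(33, endmember(35, 12), endmember(35, 2)),
               "degenerate")
  expect_error(conservative_concentration(33, m, endmember(0, 2, "dic")),
               "different tracers")
})

test_that("sources_sinks is observed minus conservative", {
  m <- endmember(35.0, 12.0)
  f <- endmember(0, 2.0)
  expect_equal(sources_sinks(4.0, 33.0, m, f), 4.0 - (2 + 33 * 10 / 35),
               tolerance = 1e-12)
  expect_equal(round(sources_sinks(4.0, 33.0, m, f), 4), -7.4286)
  # a sample on the line has delta_C 0 at any salinity
  s <- c(0, 10, 33, 35)
  expect_equal(sources_sinks(conservative_concentration(s, m, f), s, m, f),
               rep(0, 4), tolerance = 1e-12)
  expect_error(sources_sinks(Inf, 33, m, f), "non-finite")
})

test_that("conservative-mixing null and linearity hold for random endmembers", {
  set.seed(1)
  for (k in 1:200) {
    m <- endmember(runif(1, 30, 36), runif(1, 5, 2500))
    f0 <- endmember(0, runif(1, 0, 1200))
    fr <- runif(5)
    s <- fr * m$salinity + (1 - fr) * f0$salinity
    c_on_line <- conservative_concentration(s, m, f0)
    # null: on-line samples give exactly zero
    expect_lt(max(abs(sources_sinks(c_on_line, s, m, f0))), 1e-9)
    # linearity: imposing uptake u shifts delta_C by exactly -u
    u <- runif(1, 0, 10)
    expect_equal(sources_sinks(c_on_line - u, s, m, f0), rep(-u, 5),
                 tolerance = 1e-9)
    # swapping which endmember is called marine leaves the line unchanged
    expect_equal(sources_sinks(c_on_line - u, s, f0, m),
                 sources_sinks(c_on_line - u, s, m, f0), tolerance = 1e-9)
  }
})

test_that("freshwater endmember regression recovers the intercept", {
  # exact collinear points (suppress lm's perfect-fit note)
  fit <- suppressWarnings(
    freshwater_endmember_by_regression(c(30, 32, 34), c(1800, 1900, 2000)))
  expect_equal(fit$endmember$concentration, 300, tolerance = 1e-9)
  expect_equal(fit$fit$slope, 50, tolerance = 1e-9)
  expect_equal(fit$endmember$salinity, 0)
  expect_equal(fit$endmember$provenance, "regression-intercept")

  # noisy recovery: known line, intercept within 3 SE
  set.seed(7)
  s <- runif(200, 28, 35)
  conc <- 900 + 40 * s + rnorm(200, 0, 20)
  fit <- freshwater_endmember_by_regression(s, conc)
  expect_lt(abs(fit$fit$intercept - 900), 3 * fit$fit$intercept_se)
  expect_gt(fit$fit$r_squared, 0.9)

  expect_error(freshwater_endmember_by_regression(c(34, 34, 34), c(1, 2, 3)),
               "zero salinity variance")
  expect_error(freshwater_endmember_by_regression(c(30, 34), c(1, 2)),
               "insufficient")
  w <- capture_warnings(freshwater_endmember_by_regression(
    c(30, 32, 34), c(100, 200, 300)))
  expect_true(any(grepl("negative", w)))
})

test_that("contrast test is a two-tailed Welch test with sane boundaries", {
  x <- c(1, 2, 3, 4)
  expect_equal(contrast_test(x, x)$p_value, stats::t.test(x, x)$p.value)
  # identical zero-variance groups
  same <- contrast_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # clearly separated groups
  set.seed(3)
  a <- rnorm(20, 0); b <- rnorm(20, 5)
  expect_true(contrast_test(a, b)$significant)
  # alpha = 0 -> never significant
  expect_false(contrast_test(a, b, alpha = 0)$significant)
  # matches stats::t.test for both variance assumptions
  expect_equal(contrast_test(a, b)$p_value, stats::t.test(a, b)$p.value)
  expect_equal(contrast_test(a, b, var_equal = TRUE)$p_value,
               stats::t.test(a, b, var.equal = TRUE)$p.value)
  expect_error(contrast_test(1, c(1, 2)), "insufficient")
})

test_that("annual table recovers imposed drawdowns across years", {
  cfg <- synthetic_config(
    seed = 9, years = 2018:2020,
    marine_conc = c(nitrate_nitrite = 11),
    fresh_conc = c(nitrate_nitrite = 2),
    imposed_drawdown = list(SW = c(nitrate_nitrite = 5.0),
                            IW = c(nitrate_nitrite = 5.0),
                            AW = c(nitrate_nitrite = 5.0)),
    noise_sd = c(nitrate_nitrite = 0.3))
  sim <- generate_transect(cfg)
  lab <- assign_labels(sim$records, cottier_scheme())
  ss <- annual_source_sink_table(lab, tracers = "nitrate_nitrite")
  expect_equal(nrow(ss), 9)  # 3 years x 3 pairs
  expect_true(all(abs(ss$delta_C + 5.0) < 0.5))
  expect_true(all(ss$significant))
  expect_true(all(ss$p_value < 0.05))
})

test_that("conservative data give zero delta_C and missing pools give NA", {
  cfg <- synthetic_config(
    seed = 2, marine_conc = c(nitrate_nitrite = 11),
    fresh_conc = c(nitrate_nitrite = 2),
    imposed_drawdown = list(SW = c(nitrate_nitrite = 0),
                            IW = c(nitrate_nitrite = 0),
                            AW = c(nitrate_nitrite = 0)),
    noise_sd = c(nitrate_nitrite = 0))
  sim <- generate_transect(cfg)
  lab <- assign_labels(sim$records, cottier_scheme())
  ss <- annual_source_sink_table(lab, tracers = "nitrate_nitrite")
  expect_equal(ss$delta_C, rep(0, nrow(ss)), tolerance = 1e-9)

  # remove all fjord IW: that cell becomes absent, not zero
  lab2 <- lab[!(lab$region == "fjord" & lab$water_mass == "IW"), ]
  ss2 <- annual_source_sink_table(lab2, tracers = "nitrate_nitrite")
  expect_true(is.na(ss2$delta_C[ss2$pair == "AWs_vs_IW"]))
  expect_false(any(is.na(ss2$delta_C[ss2$pair == "AWs_vs_SW"])))

  # rendering of the absent cell
  lines <- write_result_table(ss2, file = NULL)
  expect_match(grep("AWs_vs_IW", lines, value = TRUE)[1], "\t-\t")
})

test_that("missing endmember config is a config error", {
  sim <- generate_transect(synthetic_config(seed = 1))
  lab <- assign_labels(sim$records, cottier_scheme())
  expect_error(
    annual_source_sink_table(lab, tracers = "nitrate_nitrite",
                             fresh_endmembers = list(dic = 900)),
    "no freshwater endmember")
})
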