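# shared fixtures: tiny bottle tables and file writers built in code

op <- options(fjordnem.quiet = TRUE)

make_bottles <- function(station = "Kb1", region = "fjord", year = 2018L,
                         depth = c(0, 50, 100), salinity = 34,
                         temperature = 4, ...) {
  df <- data.frame(station = station, region = region, year = year,
                   date = as.Date("2018-07-25"), depth = depth,
                   temperature = temperature, salinity = salinity,
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# single-water-mass recovery config: n = 50 samples per water mass,
# one tracer, drawdown imposed on SW
recovery_config <- function(seed, delta_true = 5.0, noise = 0.3) {
  synthetic_config(
    seed = seed, years = 2018L,
    n_stations_fjord = 10L, n_stations_shelf = 5L,
    depths_shelf = seq(0, 100, length.out = 10),
    marine_conc = c(nitrate_nitrite = 11),
    fresh_conc = c(nitrate_nitrite = 2.0),
    imposed_drawdown = list(SW = c(nitrate_nitrite = delta_true),
                            IW = c(nitrate_nitrite = 2.0),
                            AW = c(nitrate_nitrite = 1.0)),
    noise_sd = c(nitrate_nitrite = noise))
}
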