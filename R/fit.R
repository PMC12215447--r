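## The model-fit interface: one call that takes a bottle table and returns a
## fitted mixing/NEM object with the usual S3 methods.

#' Fit the fjord endmember-mixing / NEM model
#'
#' Runs the full analysis on a bottle table: classifies samples into water
#' masses from T/S envelopes, pools depth-weighted water-mass means per year,
#' fits the two-endmember conservative mixing model for every year × tracer ×
#' fjord/shelf contrast (marine endmember = pooled shelf AW; freshwater
#' endmember from configuration or a per-year salinity regression), screens
#' each contrast with a two-tailed Welch t-test, and converts the resulting
#' Sources−Sinks (ΔC) into drawdown rates, depth-integrated and
#' areally-upscaled net-ecosystem-metabolism estimates using a flushing time.
#'
#' @param data a bottle table ([read_bottle_table()] or
#'   [generate_transect()]`$records`).
#' @param scheme water-mass classification scheme ([cottier_scheme()]).
#' @param tracers tracer columns to analyse (default: all canonical tracers
#'   present in `data`).
#' @param pairs contrasts to compute; see [annual_source_sink_table()].
#' @param fresh_endmembers per-tracer freshwater endmember spec
#'   ([default_fresh_endmembers()]).
#' @param depth_max vertical averaging window, m (default 100; 50 and 150 are
#'   conventional sensitivity presets).
#' @param ft [flushing_spec()] or flushing time in days (default 13).
#' @param density water density for depth integration, kg m⁻³.
#' @param area_km2 fjord area for upscaling, km².
#' @param alpha significance level of the t-test screen.
#' @param var_equal use pooled-variance t-tests instead of Welch.
#' @param station_weighting `"station"` (equal station weight, default) or
#'   `"sample"`.
#' @param nem_pairs contrasts entering NEM summaries (default excludes
#'   AWs-vs-AWf).
#' @return an object of class `nem_fit` with components `sources_sinks` (a
#'   `source_sink_table`), `nem` (a `nem_table`), `endmembers` (per
#'   year × tracer the marine and freshwater endmembers used), `data` (the
#'   labeled bottle table), and the parameters.
#' @examples
#' sim <- generate_transect(scenario_paper_like(seed = 7))
#' fit <- nem_fit(sim$records, tracers = c("nitrate_nitrite", "dic"))
#' summary(fit)
#' @export
nem_fit <- function(data, scheme = cottier_scheme(),
                    tracers = NULL,
                    pairs = c("AWs_vs_IW", "AWs_vs_SW", "AWs_vs_AWf"),
                    fresh_endmembers = default_fresh_endmembers(),
                    depth_max = 100,
                    ft = flushing_spec(),
                    density = 1000, area_km2 = 231.5,
                    alpha = 0.05, var_equal = FALSE,
                    station_weighting = "station",
                    nem_pairs = c("AWs_vs_IW", "AWs_vs_SW")) {
  cl <- match.call()
  if (is.numeric(ft)) ft <- flushing_spec(ft_days = ft)
  if (is.null(tracers)) tracers <- intersect(TRACERS, names(data))
  if (length(tracers) == 0L) stop("no tracer columns found", call. = FALSE)
  labeled <- if ("water_mass" %in% names(data)) data else
    assign_labels(data, scheme)
  ss <- annual_source_sink_table(labeled, tracers = tracers, pairs = pairs,
                                 fresh_endmembers = fresh_endmembers,
                                 depth_max = depth_max, alpha = alpha,
                                 var_equal = var_equal,
                                 station_weighting = station_weighting)
  nem <- nem_table(ss, ft = ft, depth = depth_max, density = density,
                   area_km2 = area_km2, pairs = nem_pairs)

  # record endmembers per year x tracer for predict()/residuals()
  ems <- list()
  for (tr in tracers) {
    for (yr in sort(unique(labeled$year))) {
      ry <- labeled[labeled$year == yr, , drop = FALSE]
      marine <- tryCatch(
        pool_water_mass(ry, "shelf", "AW", tr, depth_max = depth_max,
                        station_weighting = station_weighting),
        error = function(e) NULL)
      spec <- fresh_endmembers[[tr]]
      fresh <- if (identical(spec, "regression")) {
        sw <- ry[ry$region == "fjord" & ry$water_mass == "SW" &
                   ry$depth <= depth_max, , drop = FALSE]
        tryCatch(freshwater_endmember_by_regression(
          sw$salinity, sw[[tr]], tracer = tr)$endmember,
          error = function(e) NULL)
      } else {
        endmember(0, as.numeric(spec), tracer = tr, provenance = "config")
      }
      if (!is.null(marine)) {
        ems[[paste(tr, yr, sep = ".")]] <- list(
          tracer = tr, year = yr,
          marine = endmember(marine$mean_sal, marine$mean_conc, tracer = tr,
                             provenance = "pooled-AWs"),
          fresh = fresh)
      }
    }
  }

  structure(list(sources_sinks = ss, nem = nem, endmembers = ems,
                 data = labeled, tracers = tracers, pairs = pairs,
                 nem_pairs = nem_pairs, depth_max = depth_max, ft = ft,
                 density = density, area_km2 = area_km2, alpha = alpha,
                 scheme = scheme, fresh_endmembers = fresh_endmembers,
                 call = cl),
            class = "nem_fit")
}

#' @export
print.nem_fit <- function(x, ...) {
  cat("Fjord endmember-mixing / NEM fit\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("%d bottle samples, years %s; tracers: %s\n",
              nrow(x$data),
              paste(range(x$data$year), collapse = "-"),
              paste(x$tracers, collapse = ", ")))
  cat(sprintf("Depth window 0-%g m; FT = %g d; density %g kg/m3; area %g km2\n",
              x$depth_max, x$ft$ft_days, x$density, x$area_km2))
  dc <- x$sources_sinks$delta_C
  cat(sprintf("Sources-Sinks: %d contrasts (%d with data), delta_C range [%s, %s] umol/kg\n",
              nrow(x$sources_sinks), sum(!is.na(dc)),
              format(round(min(dc, na.rm = TRUE), 2)),
              format(round(max(dc, na.rm = TRUE), 2))))
  invisible(x)
}

#' Extract the fitted Sources-Sinks values
#'
#' @param object a `nem_fit`.
#' @param ... unused.
#' @return named numeric vector of ΔC (µmol kg⁻¹), one element per
#'   year/tracer/pair, named `"tracer.year.pair"`.
#' @export
coef.nem_fit <- function(object, ...) {
  ss <- object$sources_sinks
  stats::setNames(ss$delta_C, paste(ss$tracer, ss$year, ss$pair, sep = "."))
}

#' Predict conservative concentrations from salinity
#'
#' Evaluates the fitted mixing line for a tracer/year at new salinities.
#'
#' @param object a `nem_fit`.
#' @param newdata data.frame with columns `salinity`, `tracer` and `year`
#'   (tracer/year may be scalar via `tracer=`, `year=` arguments instead).
#' @param tracer,year used when `newdata` is a bare numeric salinity vector.
#' @param ... unused.
#' @return numeric vector of conservative concentrations, µmol kg⁻¹.
#' @export
predict.nem_fit <- function(object, newdata, tracer = NULL, year = NULL, ...) {
  if (is.numeric(newdata)) {
    newdata <- data.frame(salinity = newdata, tracer = tracer, year = year)
  }
  stopifnot(all(c("salinity", "tracer", "year") %in% names(newdata)))
  out <- rep(NA_real_, nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    em <- object$endmembers[[paste(newdata$tracer[i], newdata$year[i],
                                   sep = ".")]]
    if (is.null(em) || is.null(em$fresh)) next
    out[i] <- conservative_concentration(newdata$salinity[i], em$marine,
                                         em$fresh)
  }
  out
}

#' Per-sample mixing residuals
#'
#' Observed minus conservative concentration for every bottle sample, using
#' that sample's year endmembers: the sample-level analogue of ΔC.
#'
#' @param object a `nem_fit`.
#' @param tracer tracer to compute residuals for (default first fitted).
#' @param ... unused.
#' @return numeric vector aligned with `object$data` rows (`NA` where the
#'   tracer or the year's endmembers are missing).
#' @export
residuals.nem_fit <- function(object, tracer = object$tracers[1], ...) {
  d <- object$data
  cons <- predict(object, data.frame(salinity = d$salinity, tracer = tracer,
                                     year = d$year))
  d[[tracer]] - cons
}

#' Summarise a NEM fit
#'
#' Computes the reporting summary: per-tracer drawdown-rate, depth-integrated
#' and areal NEM ranges over the NEM contrasts, and the mean molar C:N uptake
#' ratio when both a carbon and a nitrogen tracer were fitted. Range values
#' follow the conventional printed precision (rates to one decimal,
#' integrated mol to two decimals, grams to one decimal, tonnes to integer).
#'
#' @param object a `nem_fit`.
#' @param cn_exclusions data.frame of (year, pair) rows excluded from the C:N
#'   mean (e.g. outlier years), or `NULL`.
#' @param ... unused.
#' @return an object of class `summary.nem_fit`.
#' @export
summary.nem_fit <- function(object, cn_exclusions = NULL, ...) {
  nem <- object$nem
  per_tracer <- lapply(stats::setNames(nm = object$tracers), function(tr) {
    sub <- nem[nem$tracer == tr & !is.na(nem$rate), , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    list(rate = range(sub$rate),
         integrated_mol = range(sub$integrated_mol),
         integrated_g = range(sub$integrated_g),
         areal_tonnes = range(sub$areal_tonnes),
         n = nrow(sub))
  })
  cn <- NULL
  if (all(c("dic", "nitrate_nitrite") %in% object$tracers)) {
    cn <- tryCatch(cn_uptake_ratio(nem, exclusions = cn_exclusions),
                   error = function(e) NULL)
  }
  structure(list(per_tracer = per_tracer, cn = cn,
                 ft_days = object$ft$ft_days, depth = object$depth_max,
                 density = object$density, area_km2 = object$area_km2,
                 sources_sinks = object$sources_sinks),
            class = "summary.nem_fit")
}

#' @export
print.summary.nem_fit <- function(x, ...) {
  cat(sprintf("NEM summary (FT = %g d, 0-%g m, density %g kg/m3, area %g km2)\n",
              x$ft_days, x$depth, x$density, x$area_km2))
  for (tr in names(x$per_tracer)) {
    s <- x$per_tracer[[tr]]
    if (is.null(s)) next
    cat(sprintf("  %s (n=%d contrasts):\n", tr, s$n))
    cat(sprintf("    drawdown rate   %s to %s umol/kg/d\n",
                formatC(round(s$rate[1], 1), format = "f", digits = 1),
                formatC(round(s$rate[2], 1), format = "f", digits = 1)))
    cat(sprintf("    integrated      %s to %s mol/m2/d  (%s to %s g/m2/d)\n",
                formatC(round(s$integrated_mol[1], 2), format = "f", digits = 2),
                formatC(round(s$integrated_mol[2], 2), format = "f", digits = 2),
                formatC(round(s$integrated_g[1], 1), format = "f", digits = 1),
                formatC(round(s$integrated_g[2], 1), format = "f", digits = 1)))
    cat(sprintf("    areal           %d to %d tonnes/d\n",
                round(s$areal_tonnes[1]), round(s$areal_tonnes[2])))
  }
  if (!is.null(x$cn)) {
    cat(sprintf("  mean molar C:N uptake ratio: %.1f (n=%d)\n",
                x$cn$mean_ratio, x$cn$n))
  }
  invisible(x)
}

#' Mixing-diagram plot
#'
#' Salinity vs concentration for one tracer: bottle samples coloured by water
#' mass, with each year's fitted conservative mixing line. Points below a
#' line indicate a biogeochemical sink.
#'
#' @param x a `nem_fit`.
#' @param tracer tracer to plot (default first fitted).
#' @param years years whose mixing lines to draw (default all fitted).
#' @param ... passed to [graphics::plot()].
#' @export
plot.nem_fit <- function(x, tracer = x$tracers[1],
                         years = sort(unique(x$data$year)), ...) {
  d <- x$data[!is.na(x$data[[tracer]]), , drop = FALSE]
  wm <- factor(d$water_mass)
  cols <- grDevices::hcl.colors(max(3L, nlevels(wm)), "Dark 3")[as.integer(wm)]
  graphics::plot(d$salinity, d[[tracer]], col = cols, pch = 19,
                 xlab = "Salinity", ylab = paste(tracer, "(umol/kg)"),
                 main = "Mixing diagram", ...)
  for (yr in years) {
    em <- x$endmembers[[paste(tracer, yr, sep = ".")]]
    if (is.null(em) || is.null(em$fresh)) next
    s <- seq(min(d$salinity), max(em$marine$salinity, max(d$salinity)),
             length.out = 50)
    graphics::lines(s, conservative_concentration(s, em$marine, em$fresh),
                    lty = 2, col = "grey40")
  }
  graphics::legend("topleft", legend = levels(wm), pch = 19,
                   col = grDevices::hcl.colors(max(3L, nlevels(wm)),
                                               "Dark 3")[seq_len(nlevels(wm))],
                   bty = "n")
  invisible(x)
}

#' Simulate bottle tables from a fitted model
#'
#' Draws synthetic transects whose endmembers and imposed drawdowns are the
#' fitted ones (per-water-mass |ΔC| of the first fitted year, floored at 0),
#' with Gaussian noise equal to the pooled sample s.d. — useful as a
#' parametric-bootstrap check that the pipeline recovers what it estimated.
#'
#' @param object a `nem_fit` (must include fitted nitrate and/or other
#'   tracers with complete endmembers for the reference year).
#' @param nsim number of simulated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `nsim` bottle tables.
#' @export
simulate.nem_fit <- function(object, nsim = 1, seed = 1L, ...) {
  ss <- object$sources_sinks
  yr <- sort(unique(ss$year[!is.na(ss$delta_C)]))[1]
  if (is.na(yr)) stop("no complete year to simulate from", call. = FALSE)
  tracers <- intersect(object$tracers, names(synthetic_config()$marine_conc))
  marine_conc <- fresh_conc <- c()
  dd <- list(SW = c(), IW = c(), AW = c())
  noise <- c()
  for (tr in tracers) {
    em <- object$endmembers[[paste(tr, yr, sep = ".")]]
    if (is.null(em) || is.null(em$fresh)) next
    marine_conc[tr] <- em$marine$concentration
    fresh_conc[tr] <- max(em$fresh$concentration, 0)
    for (pr in names(PAIR_FJORD_LABEL)) {
      v <- ss$delta_C[ss$year == yr & ss$tracer == tr & ss$pair == pr]
      dd[[PAIR_FJORD_LABEL[[pr]]]][tr] <-
        if (length(v) == 1L && !is.na(v)) max(-v, 0) else 0
    }
    sdv <- stats::sd(object$data[[tr]][object$data$year == yr &
                                         object$data$region == "fjord"],
                     na.rm = TRUE)
    noise[tr] <- if (is.finite(sdv)) sdv / 4 else 0
  }
  if (length(marine_conc) == 0L) {
    stop("no complete endmember pairs to simulate from", call. = FALSE)
  }
  lapply(seq_len(nsim), function(i) {
    cfg <- synthetic_config(seed = seed + i - 1L, years = yr,
                            marine_conc = marine_conc,
                            fresh_conc = fresh_conc,
                            imposed_drawdown = dd, noise_sd = noise,
                            scheme = object$scheme)
    generate_transect(cfg)$records
  })
}
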