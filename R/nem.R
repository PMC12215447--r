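## Net ecosystem metabolism: converting Sources-Sinks (delta_C) into
## drawdown rates via flushing time, depth-integrating, and upscaling to the
## fjord area. Under the steady-state box model the biogeochemical term must
## balance exchange with the sea, so NEM ~= -(Sources - Sinks)/FT; positive
## rates mean net drawdown (autotrophic fjord).

#' Flushing-time specification
#'
#' Either a fixed flushing time in days (default 13, the mean of
#' hydrodynamic-model estimates for a West Spitsbergen glacial fjord) or a
#' LOICZ/Knudsen salt-balance estimate from fjord volume, freshwater inflow
#' and the fjord/ocean salinities.
#'
#' @param ft_days flushing time in days (> 0); ignored when `method="loicz"`.
#' @param method `"fixed"` or `"loicz"`.
#' @param volume fjord volume, m³ (loicz).
#' @param q_freshwater freshwater inflow, m³ s⁻¹ (loicz).
#' @param s_ocean,s_fjord inflowing/outflowing salinities (loicz;
#'   `s_ocean > s_fjord >= 0`).
#' @return object of class `flushing_spec` with resolved `ft_days`.
#' @export
flushing_spec <- function(ft_days = 13, method = c("fixed", "loicz"),
                          volume = NULL, q_freshwater = NULL,
                          s_ocean = NULL, s_fjord = NULL) {
  method <- match.arg(method)
  if (method == "loicz") {
    ft_days <- loicz_flushing_time(volume, q_freshwater, s_ocean, s_fjord)
  }
  stopifnot(is.finite(ft_days), ft_days > 0)
  structure(list(ft_days = ft_days, method = method, volume = volume,
                 q_freshwater = q_freshwater, s_ocean = s_ocean,
                 s_fjord = s_fjord),
            class = "flushing_spec")
}

#' @export
print.flushing_spec <- function(x, ...) {
  cat(sprintf("Flushing time: %.2f days (%s)\n", x$ft_days, x$method))
  invisible(x)
}

#' LOICZ/Knudsen salt-balance flushing time
#'
#' Steady-state salt balance: freshwater inflow `Q_fw` is balanced by an
#' outflow of fjord water at salinity `s_fjord` and an inflow of ocean water
#' at `s_ocean`, giving `Q_out = Q_fw * s_ocean / (s_ocean - s_fjord)` and a
#' flushing time `FT = V / Q_out`.
#'
#' @param volume fjord volume, m³ (> 0).
#' @param q_freshwater freshwater inflow, m³ s⁻¹ (> 0).
#' @param s_ocean,s_fjord salinities, `s_ocean > s_fjord >= 0`.
#' @return flushing time in days.
#' @examples
#' loicz_flushing_time(2e10, 100, 35, 34.65)  # 23.15 d
#' @export
loicz_flushing_time <- function(volume, q_freshwater, s_ocean, s_fjord) {
  stopifnot(is.finite(volume), volume > 0,
            is.finite(q_freshwater), q_freshwater > 0,
            is.finite(s_ocean), is.finite(s_fjord), s_fjord >= 0)
  if (s_fjord >= s_ocean) {
    stop("degenerate salt balance: s_fjord must be < s_ocean", call. = FALSE)
  }
  q_out <- q_freshwater * s_ocean / (s_ocean - s_fjord)
  (volume / q_out) / 86400
}

#' Drawdown rate from Sources-Sinks and flushing time
#'
#' `rate = -delta_C / FT`: positive for sinks (negative ΔC), in
#' µmol kg⁻¹ d⁻¹. This is the NEM proxy on a per-mass basis.
#'
#' @param delta_C Sources−Sinks, µmol kg⁻¹ (vectorised; `NA` propagates).
#' @param ft a [flushing_spec()] or a number of days.
#' @return drawdown rate, µmol kg⁻¹ d⁻¹.
#' @examples
#' drawdown_rate(-72.8, 13)  # 5.6
#' @export
drawdown_rate <- function(delta_C, ft = flushing_spec()) {
  if (is.numeric(ft)) ft <- flushing_spec(ft_days = ft)
  stopifnot(inherits(ft, "flushing_spec"))
  if (any(is.infinite(delta_C) | is.nan(delta_C), na.rm = TRUE)) {
    stop("non-finite delta_C", call. = FALSE)
  }
  -delta_C / ft$ft_days
}

#' Depth-integrate a drawdown rate
#'
#' Converts a per-mass rate into an areal rate over the productive layer:
#' `mol m⁻² d⁻¹ = rate * density * depth * 1e-6`, and grams using the
#' tracer's elemental molar mass (N 14.007, C 12.011, ...).
#'
#' @param rate drawdown rate, µmol kg⁻¹ d⁻¹ (vectorised).
#' @param depth integration depth, m (> 0), default 100.
#' @param density water density, kg m⁻³ (> 0), default 1000 (making
#'   µmol kg⁻¹ numerically equal to µmol L⁻¹).
#' @param tracer tracer name used to look up the molar mass, or supply
#'   `molar_mass` directly.
#' @param molar_mass g mol⁻¹; overrides `tracer`.
#' @return data.frame with columns `mol_m2_d` and `g_m2_d`.
#' @examples
#' integrate_drawdown(5.6, tracer = "dic")  # 0.56 mol, 6.73 g C m-2 d-1
#' @export
integrate_drawdown <- function(rate, depth = 100, density = 1000,
                               tracer = "nitrate_nitrite",
                               molar_mass = NULL) {
  stopifnot(depth > 0, density > 0)
  if (is.null(molar_mass)) molar_mass <- tracer_molar_mass(tracer)
  mol <- rate * density * depth * 1e-6
  data.frame(mol_m2_d = mol, g_m2_d = mol * molar_mass)
}

#' Upscale an areal rate to the fjord area
#'
#' `tonnes d⁻¹ = g m⁻² d⁻¹ × area_km2` (1 g m⁻² over 1 km² is 1 tonne).
#'
#' @param integrated_g areal rate, g m⁻² d⁻¹ (vectorised).
#' @param area_km2 fjord area, km² (> 0), default 231.5.
#' @return tonnes d⁻¹.
#' @examples
#' upscale_areal(0.8295, 231.5)  # 192 tonnes d-1
#' @export
upscale_areal <- function(integrated_g, area_km2 = 231.5) {
  stopifnot(area_km2 > 0)
  integrated_g * area_km2
}

#' Build a NEM table from a source/sink table
#'
#' Applies [drawdown_rate()], [integrate_drawdown()] and [upscale_areal()] to
#' every row of a source/sink table. By default only the shelf-AW-vs-IW and
#' shelf-AW-vs-SW contrasts enter (the AWs-vs-AWf contrast compares the same
#' water mass inside and outside the fjord and is excluded from NEM
#' summaries).
#'
#' @param ss a `source_sink_table` ([annual_source_sink_table()]), or any
#'   data.frame with `year`, `tracer`, `pair`, `delta_C`.
#' @param ft [flushing_spec()] or days.
#' @param depth,density,area_km2 passed to the integration chain.
#' @param pairs contrasts to retain.
#' @return a `nem_table` data.frame with `rate` (µmol kg⁻¹ d⁻¹),
#'   `integrated_mol` (mol m⁻² d⁻¹), `integrated_g` (g m⁻² d⁻¹),
#'   `areal_tonnes` (tonnes d⁻¹) and the parameters used.
#' @export
nem_table <- function(ss, ft = flushing_spec(), depth = 100, density = 1000,
                      area_km2 = 231.5,
                      pairs = c("AWs_vs_IW", "AWs_vs_SW")) {
  if (is.numeric(ft)) ft <- flushing_spec(ft_days = ft)
  stopifnot(is.data.frame(ss),
            all(c("year", "tracer", "pair", "delta_C") %in% names(ss)))
  keep <- ss$pair %in% pairs
  out <- as.data.frame(ss)[keep, c("year", "tracer", "pair", "delta_C"),
                           drop = FALSE]
  if ("significant" %in% names(ss)) out$significant <- ss$significant[keep]
  out$rate <- drawdown_rate(out$delta_C, ft)  # NA propagates
  ints <- lapply(seq_len(nrow(out)), function(i) {
    if (is.na(out$rate[i])) return(c(NA_real_, NA_real_))
    v <- integrate_drawdown(out$rate[i], depth = depth, density = density,
                            tracer = out$tracer[i])
    c(v$mol_m2_d, v$g_m2_d)
  })
  ints <- do.call(rbind, ints)
  out$integrated_mol <- if (nrow(out)) ints[, 1] else numeric(0)
  out$integrated_g <- if (nrow(out)) ints[, 2] else numeric(0)
  out$areal_tonnes <- upscale_areal(out$integrated_g, area_km2)
  out$depth <- depth
  out$density <- density
  out$area_km2 <- area_km2
  out$ft_days <- ft$ft_days
  rownames(out) <- NULL
  class(out) <- c("nem_table", "data.frame")
  out
}

#' Mean molar C:N uptake ratio across matched drawdown estimates
#'
#' Matches DIC and nitrate+nitrite drawdown rates by (year, pair), keeps the
#' matches where both rates are positive (both tracers drawn down), drops any
#' explicitly excluded (year, pair) combinations (e.g. known outlier years),
#' and returns the arithmetic mean of the per-pair C:N rate ratios.
#'
#' @param nem a `nem_table` containing both a carbon and a nitrogen tracer.
#' @param c_tracer,n_tracer tracer names (defaults `"dic"`,
#'   `"nitrate_nitrite"`).
#' @param exclusions data.frame with columns `year` and `pair` to drop, or
#'   `NULL`.
#' @return list with `mean_ratio`, `n`, and `ratios` (a data.frame of the
#'   matched pairs).
#' @export
cn_uptake_ratio <- function(nem, c_tracer = "dic",
                            n_tracer = "nitrate_nitrite",
                            exclusions = NULL) {
  stopifnot(is.data.frame(nem), all(c("year", "pair", "tracer", "rate") %in%
                                      names(nem)))
  cpart <- nem[nem$tracer == c_tracer, c("year", "pair", "rate")]
  npart <- nem[nem$tracer == n_tracer, c("year", "pair", "rate")]
  names(cpart)[3] <- "c_rate"
  names(npart)[3] <- "n_rate"
  m <- merge(cpart, npart, by = c("year", "pair"))
  m <- m[is.finite(m$c_rate) & is.finite(m$n_rate) &
           m$c_rate > 0 & m$n_rate > 0, , drop = FALSE]
  if (!is.null(exclusions) && nrow(m) > 0L) {
    drop <- paste(m$year, m$pair) %in% paste(exclusions$year, exclusions$pair)
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) == 0L) {
    stop("insufficient data: no matched (year, pair) with positive C and N ",
         "drawdown rates", call. = FALSE)
  }
  m$ratio <- m$c_rate / m$n_rate
  list(mean_ratio = mean(m$ratio), n = nrow(m), ratios = m)
}
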