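## Two-endmember conservative mixing model.
##
## Water masses inside the fjord are assumed to form solely by dilution of
## shelf Atlantic Water with glacial freshwater. Salinity then fixes the
## mixing fraction, and the concentration a conservative tracer would have is
## a linear function of salinity between the two endmembers. The departure of
## the observed concentration from that line,
##   delta_C = C_obs - [C_0 + (S_obs - S_0) (C_AW - C_0)/(S_AW - S_0)],
## is the net biogeochemical Sources - Sinks: negative = sink, positive =
## source.

#' Construct a mixing endmember
#'
#' A (salinity, concentration) anchor for the conservative mixing line.
#'
#' @param salinity practical salinity (≥ 0).
#' @param concentration tracer concentration in µmol kg⁻¹ (≥ 0).
#' @param tracer tracer name.
#' @param provenance free-text origin (e.g. `"config"`,
#'   `"regression-intercept"`, `"pooled-AWs"`).
#' @return an object of class `endmember`.
#' @export
endmember <- function(salinity, concentration, tracer = NA_character_,
                      provenance = "config") {
  stopifnot(is.finite(salinity), salinity >= 0, is.finite(concentration))
  if (concentration < 0) {
    warning("endmember concentration is negative (", format(concentration),
            " umol/kg, tracer ", tracer, ")")
  }
  structure(list(salinity = as.numeric(salinity),
                 concentration = as.numeric(concentration),
                 tracer = tracer, provenance = provenance),
            class = "endmember")
}

#' @export
print.endmember <- function(x, ...) {
  cat(sprintf("Endmember [%s]: S=%.3f, C=%.3f umol/kg (%s)\n",
              x$tracer, x$salinity, x$concentration, x$provenance))
  invisible(x)
}

#' Conservative concentration predicted from salinity
#'
#' Linear two-endmember mixing: the concentration a sample of salinity
#' `S_obs` would have if its tracer changed only by dilution between the
#' marine and freshwater endmembers,
#' \deqn{C_{cons} = C_0 + (S_{obs} - S_0)\,(C_{AW} - C_0)/(S_{AW} - S_0).}
#' Extrapolation beyond the endmember salinities is permitted but logged.
#'
#' @param S_obs observed salinity (vectorised).
#' @param marine,fresh [endmember()] objects; their salinities must differ.
#' @return predicted conservative concentration(s), µmol kg⁻¹.
#' @examples
#' m <- endmember(35, 12); f <- endmember(0, 2)
#' conservative_concentration(33, m, f)  # 11.4286
#' @export
conservative_concentration <- function(S_obs, marine, fresh) {
  stopifnot(inherits(marine, "endmember"), inherits(fresh, "endmember"))
  if (!is.na(marine$tracer) && !is.na(fresh$tracer) &&
      !identical(tolower(marine$tracer), tolower(fresh$tracer))) {
    stop("endmembers are for different tracers (", marine$tracer, " vs ",
         fresh$tracer, ")", call. = FALSE)
  }
  if (marine$salinity == fresh$salinity) {
    stop("degenerate mixing line: endmember salinities are equal",
         call. = FALSE)
  }
  lo <- min(marine$salinity, fresh$salinity)
  hi <- max(marine$salinity, fresh$salinity)
  if (any(S_obs < lo | S_obs > hi, na.rm = TRUE)) {
    fn_warnlog("salinity outside the endmember range [", lo, ", ", hi,
               "]: extrapolating the mixing line")
  }
  fresh$concentration + (S_obs - fresh$salinity) *
    (marine$concentration - fresh$concentration) /
    (marine$salinity - fresh$salinity)
}

#' Biogeochemical sources minus sinks (ΔC)
#'
#' Observed minus conservatively predicted concentration. Negative values
#' mean the fjord water mass is a net sink relative to conservative mixing;
#' positive, a net source.
#'
#' @param C_obs observed concentration, µmol kg⁻¹ (vectorised with `S_obs`).
#' @inheritParams conservative_concentration
#' @return ΔC = C_obs − C_cons, µmol kg⁻¹.
#' @examples
#' m <- endmember(35, 12); f <- endmember(0, 2)
#' sources_sinks(4.0, 33, m, f)  # -7.4286
#' @export
sources_sinks <- function(C_obs, S_obs, marine, fresh) {
  if (any(!is.finite(C_obs))) stop("non-finite C_obs", call. = FALSE)
  C_obs - conservative_concentration(S_obs, marine, fresh)
}

#' Freshwater endmember from a salinity regression intercept
#'
#' Ordinary least squares of concentration on salinity; the Y-intercept (the
#' concentration extrapolated to salinity 0) is the freshwater endmember.
#' Used for DIC, whose meltwater concentration is not measured directly.
#' Negative intercepts are returned with a warning, not clamped.
#'
#' @param salinity,concentration numeric vectors (≥ 3 finite pairs spanning a
#'   salinity range > 0).
#' @param tracer tracer name recorded on the endmember.
#' @return list with `endmember` (an [endmember()] at salinity 0) and `fit`
#'   (slope, intercept, intercept_se, r_squared, n).
#' @export
freshwater_endmember_by_regression <- function(salinity, concentration,
                                               tracer = "dic") {
  keep <- is.finite(salinity) & is.finite(concentration)
  salinity <- salinity[keep]; concentration <- concentration[keep]
  if (length(salinity) < 3L) {
    stop("insufficient data: need >= 3 samples for the endmember regression",
         call. = FALSE)
  }
  if (stats::var(salinity) == 0) {
    stop("insufficient data: zero salinity variance, intercept undefined",
         call. = FALSE)
  }
  m <- stats::lm(concentration ~ salinity)
  sm <- summary(m)
  intercept <- unname(stats::coef(m)[1])
  if (intercept < 0) {
    warning("regression freshwater endmember is negative (",
            format(intercept), " umol/kg)")
  }
  list(
    endmember = endmember(0, intercept, tracer = tracer,
                          provenance = "regression-intercept"),
    fit = list(slope = unname(stats::coef(m)[2]),
               intercept = intercept,
               intercept_se = unname(sm$coefficients[1, 2]),
               r_squared = sm$r.squared,
               n = length(salinity))
  )
}

#' Two-tailed contrast test between two sample groups
#'
#' Screens whether two pools of bottle concentrations differ: Welch's
#' unequal-variance two-tailed t-test by default, or the pooled
#' equal-variance test. Two zero-variance groups with equal means return
#' p = 1.
#'
#' @param group_a,group_b numeric vectors (≥ 2 finite values each).
#' @param alpha significance level (default 0.05).
#' @param var_equal use the pooled equal-variance test instead of Welch.
#' @return list with `p_value`, `significant` (p < alpha), `statistic`, `df`.
#' @export
contrast_test <- function(group_a, group_b, alpha = 0.05, var_equal = FALSE) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("insufficient data: each group needs >= 2 finite values",
         call. = FALSE)
  }
  stopifnot(alpha >= 0, alpha <= 1)
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(p_value = 1, significant = FALSE,
                  statistic = 0, df = NA_real_))
    }
    return(list(p_value = 0, significant = 0 < alpha,
                statistic = Inf, df = NA_real_))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal,
                      alternative = "two.sided")
  list(p_value = unname(tt$p.value),
       significant = unname(tt$p.value) < alpha,
       statistic = unname(tt$statistic),
       df = unname(tt$parameter))
}

#' Default freshwater endmember configuration
#'
#' Per-tracer freshwater (salinity 0) endmember settings: glacial-river mean
#' concentrations for the nutrients (µmol kg⁻¹: ammonium 1.44, nitrate +
#' nitrite 2.00, phosphate 0.064, silicic acid 9.77) and `"regression"` for
#' DIC, whose endmember is re-estimated each year as the Y-intercept of a
#' salinity-DIC regression in Surface Water.
#'
#' @return named list mapping tracer → numeric concentration or
#'   `"regression"`.
#' @export
default_fresh_endmembers <- function() {
  list(nitrate_nitrite = 2.00, ammonium = 1.44, phosphate = 0.064,
       silicic_acid = 9.77, dic = "regression")
}

## pairs: marine water mass on the shelf vs fjord water mass
PAIR_FJORD_LABEL <- c(AWs_vs_IW = "IW", AWs_vs_SW = "SW", AWs_vs_AWf = "AW")

#' Annual source/sink table from labeled bottle data
#'
#' For each year × tracer × fjord/shelf contrast, applies the mixing model:
#' the marine endmember is the pooled shelf AW (concentration and salinity
#' depth-weight-averaged per station, then averaged across stations); the
#' observation is the pooled fjord water mass (IW, SW, or fjord AW); the
#' freshwater endmember comes from `fresh_endmembers` — a fixed concentration
#' at salinity 0, or `"regression"` for a per-year intercept of the tracer on
#' salinity among fjord SW samples. Years or water masses with no data yield
#' absent rows (`NA`), never zeros. Each contrast is screened with
#' [contrast_test()] on the raw bottle concentrations within the depth
#' window.
#'
#' @param records labeled bottle table ([assign_labels()]).
#' @param tracers tracer columns to analyse.
#' @param pairs subset of `c("AWs_vs_IW", "AWs_vs_SW", "AWs_vs_AWf")`.
#' @param fresh_endmembers per-tracer freshwater endmember spec; see
#'   [default_fresh_endmembers()].
#' @param depth_max vertical averaging window (m), default 100.
#' @param alpha significance level for the t-test screen.
#' @param var_equal use pooled-variance t-tests.
#' @param station_weighting passed to [pool_water_mass()].
#' @return a `source_sink_table` data.frame with columns `year`, `tracer`,
#'   `pair`, `S_obs`, `C_obs`, `C_cons`, `delta_C`, `n_fjord`, `n_shelf`,
#'   `p_value`, `significant`, `fresh_conc`.
#' @export
annual_source_sink_table <- function(records,
                                     tracers = c("nitrate_nitrite", "dic"),
                                     pairs = names(PAIR_FJORD_LABEL),
                                     fresh_endmembers = default_fresh_endmembers(),
                                     depth_max = 100, alpha = 0.05,
                                     var_equal = FALSE,
                                     station_weighting = "station") {
  stopifnot(is.data.frame(records), "water_mass" %in% names(records))
  pairs <- match.arg(pairs, names(PAIR_FJORD_LABEL), several.ok = TRUE)
  years <- sort(unique(records$year))
  rows <- list()
  for (tr in tracers) {
    spec <- fresh_endmembers[[tr]]
    if (is.null(spec)) {
      stop("no freshwater endmember configured for tracer '", tr, "'",
           call. = FALSE)
    }
    for (yr in years) {
      ry <- records[records$year == yr, , drop = FALSE]
      marine <- tryCatch(
        pool_water_mass(ry, "shelf", "AW", tr, depth_max = depth_max,
                        station_weighting = station_weighting),
        error = function(e) NULL)
      fresh <- if (identical(spec, "regression")) {
        sw <- ry[ry$region == "fjord" & ry$water_mass == "SW" &
                   ry$depth <= depth_max, , drop = FALSE]
        tryCatch(
          freshwater_endmember_by_regression(sw$salinity, sw[[tr]],
                                             tracer = tr)$endmember,
          error = function(e) NULL)
      } else {
        endmember(0, as.numeric(spec), tracer = tr, provenance = "config")
      }
      for (pr in pairs) {
        fj_label <- PAIR_FJORD_LABEL[[pr]]
        obs <- tryCatch(
          pool_water_mass(ry, "fjord", fj_label, tr, depth_max = depth_max,
                          station_weighting = station_weighting),
          error = function(e) NULL)
        row <- data.frame(year = yr, tracer = tr, pair = pr,
                          S_obs = NA_real_, C_obs = NA_real_,
                          C_cons = NA_real_, delta_C = NA_real_,
                          n_fjord = NA_integer_, n_shelf = NA_integer_,
                          p_value = NA_real_, significant = NA,
                          fresh_conc = if (is.null(fresh)) NA_real_ else
                            fresh$concentration,
                          stringsAsFactors = FALSE)
        if (!is.null(marine) && !is.null(obs) && !is.null(fresh)) {
          m_em <- endmember(marine$mean_sal, marine$mean_conc, tracer = tr,
                            provenance = "pooled-AWs")
          row$S_obs <- obs$mean_sal
          row$C_obs <- obs$mean_conc
          row$C_cons <- conservative_concentration(obs$mean_sal, m_em, fresh)
          row$delta_C <- row$C_obs - row$C_cons
          row$n_fjord <- obs$n
          row$n_shelf <- marine$n
          ct <- tryCatch(contrast_test(obs$samples, marine$samples,
                                       alpha = alpha, var_equal = var_equal),
                         error = function(e) NULL)
          if (!is.null(ct)) {
            row$p_value <- ct$p_value
            row$significant <- ct$significant
          }
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "depth_max") <- depth_max
  attr(out, "alpha") <- alpha
  class(out) <- c("source_sink_table", "data.frame")
  out
}
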