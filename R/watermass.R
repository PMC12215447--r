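## Water-mass classification from rectangular T/S envelopes, and
## depth-weighted pooling of bottle profiles.

#' Construct a water-mass envelope
#'
#' A rectangular region of temperature-salinity space with optional bounds.
#' Minima are inclusive, maxima exclusive. At least one bound must be given.
#'
#' @param name water-mass label (e.g. `"AW"`).
#' @param tmin,tmax temperature bounds (°C), `NA` for unbounded.
#' @param smin,smax practical-salinity bounds, `NA` for unbounded.
#' @param priority integer rank; lower wins when envelopes overlap.
#' @return an object of class `wm_envelope`.
#' @export
wm_envelope <- function(name, tmin = NA, tmax = NA, smin = NA, smax = NA,
                        priority = 1L) {
  b <- c(tmin = tmin, tmax = tmax, smin = smin, smax = smax)
  if (all(is.na(b))) {
    stop("envelope '", name, "' has no bounds", call. = FALSE)
  }
  if (!is.na(tmin) && !is.na(tmax) && tmin > tmax) {
    stop("envelope '", name, "': tmin > tmax", call. = FALSE)
  }
  if (!is.na(smin) && !is.na(smax) && smin > smax) {
    stop("envelope '", name, "': smin > smax", call. = FALSE)
  }
  structure(list(name = as.character(name),
                 tmin = as.numeric(tmin), tmax = as.numeric(tmax),
                 smin = as.numeric(smin), smax = as.numeric(smax),
                 priority = as.integer(priority)),
            class = "wm_envelope")
}

#' Construct a water-mass classification scheme
#'
#' An ordered set of [wm_envelope()]s with a fallback label for samples that
#' match none. Envelopes are ordered by priority, which must be unique.
#'
#' @param envelopes list of `wm_envelope` objects.
#' @param fallback_label label for unmatched samples (default `"other"`).
#' @return an object of class `wm_scheme`.
#' @export
wm_scheme <- function(envelopes, fallback_label = "other") {
  stopifnot(length(envelopes) > 0L)
  stopifnot(all(vapply(envelopes, inherits, logical(1), "wm_envelope")))
  pr <- vapply(envelopes, `[[`, integer(1), "priority")
  if (anyDuplicated(pr)) {
    stop("envelope priorities must be unique within a scheme", call. = FALSE)
  }
  envelopes <- envelopes[order(pr)]
  structure(list(envelopes = envelopes,
                 fallback_label = as.character(fallback_label)),
            class = "wm_scheme")
}

#' @export
print.wm_scheme <- function(x, ...) {
  cat("Water-mass scheme (", length(x$envelopes), " envelopes, fallback '",
      x$fallback_label, "'):\n", sep = "")
  for (e in x$envelopes) {
    cat(sprintf("  %-4s T in [%s, %s)  S in [%s, %s)  priority %d\n",
                e$name,
                ifelse(is.na(e$tmin), "-Inf", format(e$tmin)),
                ifelse(is.na(e$tmax), "Inf", format(e$tmax)),
                ifelse(is.na(e$smin), "-Inf", format(e$smin)),
                ifelse(is.na(e$smax), "Inf", format(e$smax)),
                e$priority))
  }
  invisible(x)
}

#' Default water-mass scheme for the West Spitsbergen shelf and fjords
#'
#' Rectangular T/S envelopes in the style of the standard West Spitsbergen
#' water-mass classification: Atlantic Water (AW), Transformed Atlantic Water
#' (TAW), Arctic Water (ArW), Intermediate Water (IW) and Surface Water (SW).
#' These defaults are a convenience; envelope values are analysis choices and
#' can be edited or supplied via a config file ([read_wm_scheme()]).
#'
#' @return a `wm_scheme`.
#' @export
cottier_scheme <- function() {
  wm_scheme(list(
    wm_envelope("AW",  tmin = 3.0,            smin = 34.9,              priority = 1L),
    wm_envelope("TAW", tmin = 1.0, tmax = 3.0, smin = 34.7,             priority = 2L),
    wm_envelope("ArW", tmin = -1.5, tmax = 1.0, smin = 34.3, smax = 34.8, priority = 3L),
    wm_envelope("IW",  tmin = 1.0,            smin = 34.0, smax = 34.7, priority = 4L),
    wm_envelope("SW",  tmin = 1.0,            smax = 34.0,              priority = 5L)
  ))
}

#' Read a water-mass scheme from a YAML config section
#'
#' Expects a list of `{name, tmin, tmax, smin, smax, priority}` entries, e.g.
#' under a `water_masses:` key.
#'
#' @param x path to a YAML file, or an already-parsed list.
#' @param fallback_label label for unmatched samples.
#' @return a `wm_scheme`.
#' @export
read_wm_scheme <- function(x, fallback_label = "other") {
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.null(x$water_masses)) x <- x$water_masses
  envs <- lapply(x, function(e) {
    wm_envelope(e$name, tmin = e$tmin %||% NA, tmax = e$tmax %||% NA,
                smin = e$smin %||% NA, smax = e$smax %||% NA,
                priority = e$priority)
  })
  wm_scheme(envs, fallback_label = fallback_label)
}

#' Classify a sample into a water mass
#'
#' Returns the label of the highest-priority envelope whose bounds all hold
#' (minima inclusive, maxima exclusive), or the scheme's fallback label if
#' none match. Vectorised over `temperature`/`salinity`.
#'
#' @param temperature °C.
#' @param salinity practical salinity.
#' @param scheme a [wm_scheme()].
#' @return character vector of labels.
#' @examples
#' classify_sample(4.0, 35.0, cottier_scheme())  # "AW"
#' @export
classify_sample <- function(temperature, salinity, scheme) {
  stopifnot(inherits(scheme, "wm_scheme"))
  if (length(temperature) != length(salinity)) {
    stop("temperature and salinity lengths differ", call. = FALSE)
  }
  if (any(!is.finite(temperature)) || any(!is.finite(salinity))) {
    stop("non-finite temperature or salinity", call. = FALSE)
  }
  label <- rep(scheme$fallback_label, length(temperature))
  assigned <- rep(FALSE, length(temperature))
  for (e in scheme$envelopes) {  # already priority-ordered
    ok <- !assigned
    if (!is.na(e$tmin)) ok <- ok & temperature >= e$tmin
    if (!is.na(e$tmax)) ok <- ok & temperature < e$tmax
    if (!is.na(e$smin)) ok <- ok & salinity >= e$smin
    if (!is.na(e$smax)) ok <- ok & salinity < e$smax
    label[ok] <- e$name
    assigned <- assigned | ok
  }
  label
}

#' Attach water-mass labels to a bottle table
#'
#' Adds a `water_mass` column via [classify_sample()] and logs per-label
#' counts.
#'
#' @param records bottle-table `data.frame` with `temperature` and `salinity`.
#' @param scheme a [wm_scheme()].
#' @return the bottle table with a `water_mass` column.
#' @export
assign_labels <- function(records, scheme) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    records$water_mass <- character(0)
    return(records)
  }
  records$water_mass <- classify_sample(records$temperature, records$salinity,
                                        scheme)
  counts <- table(records$water_mass)
  fn_info("water-mass labels: ",
          paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                collapse = ", "))
  records
}

#' Depth-weighted (trapezoidal) vertical mean
#'
#' Vertically averages a bottle profile over the window `[0, depth_max]`:
#' the trapezoidal integral of value against depth from the shallowest
#' retained sample to the deepest (samples deeper than `depth_max` are
#' dropped), divided by that depth span. Duplicate depths are averaged first
#' and logged. A single retained sample returns its value.
#'
#' @param depth numeric vector of depths (m, positive down).
#' @param value numeric vector of the same length; `NA` pairs are dropped.
#' @param depth_max bottom of the averaging window (m), default 100.
#' @return scalar mean value over the window.
#' @examples
#' depth_weighted_mean(c(0, 50, 100), c(1, 2, 3))          # 2.0
#' depth_weighted_mean(c(0, 20, 100), c(4, 2, 1))          # 1.8
#' @export
depth_weighted_mean <- function(depth, value, depth_max = 100) {
  stopifnot(length(depth) == length(value), depth_max > 0)
  keep <- !is.na(depth) & !is.na(value) & depth <= depth_max
  depth <- depth[keep]; value <- value[keep]
  if (length(depth) == 0L) {
    stop("no samples within the depth window [0, ", depth_max, "]",
         call. = FALSE)
  }
  if (anyDuplicated(depth)) {
    value <- tapply(value, depth, mean)
    depth <- as.numeric(names(value))
    value <- as.numeric(value)
    fn_warnlog("duplicate depths averaged in depth_weighted_mean")
  }
  o <- order(depth)
  depth <- depth[o]; value <- value[o]
  n <- length(depth)
  if (n == 1L) return(value)
  span <- depth[n] - depth[1]
  area <- sum(diff(depth) * (value[-1] + value[-n]) / 2)
  area / span
}

#' Pool a water mass into a mean concentration and salinity
#'
#' Computes the pooled mean used as an observed value (or marine endmember)
#' in the mixing model: per-station depth-weighted means over `[0,
#' depth_max]` are computed first, then averaged across stations with equal
#' weight. `sd_conc` and `n` are reported at the bottle-sample level (the
#' inputs of the t-test screen). With `station_weighting = "sample"` the
#' pooled mean is the plain mean over retained bottles instead.
#'
#' @param records labeled bottle table (see [assign_labels()]).
#' @param region one of `"fjord"`, `"shelf"`, `"fram_strait"`.
#' @param label water-mass label to pool.
#' @param tracer tracer column name.
#' @param depth_max averaging window bottom (m).
#' @param station_weighting `"station"` (default) or `"sample"`.
#' @return a list of class `pooled_mean` with fields `water_mass`, `region`,
#'   `tracer`, `mean_conc`, `sd_conc`, `mean_sal`, `n`, `stations`, and
#'   `samples` (the retained per-bottle concentrations).
#' @export
pool_water_mass <- function(records, region, label, tracer,
                            depth_max = 100,
                            station_weighting = c("station", "sample")) {
  station_weighting <- match.arg(station_weighting)
  stopifnot(is.data.frame(records), "water_mass" %in% names(records))
  if (!tracer %in% names(records)) {
    stop("empty pool: tracer '", tracer, "' not present (region=", region,
         ", label=", label, ")", call. = FALSE)
  }
  sel <- records$region == region & records$water_mass == label &
    !is.na(records[[tracer]]) & !is.na(records$depth) &
    records$depth <= depth_max
  sub <- records[sel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("empty pool: no samples for region=", region, ", label=", label,
         ", tracer=", tracer, " within ", depth_max, " m", call. = FALSE)
  }
  if (station_weighting == "station") {
    by_st <- split(sub, sub$station)
    conc_st <- vapply(by_st, function(d)
      depth_weighted_mean(d$depth, d[[tracer]], depth_max), numeric(1))
    sal_st <- vapply(by_st, function(d)
      depth_weighted_mean(d$depth, d$salinity, depth_max), numeric(1))
    mean_conc <- mean(conc_st)
    mean_sal <- mean(sal_st)
  } else {
    mean_conc <- mean(sub[[tracer]])
    mean_sal <- mean(sub$salinity)
  }
  n <- nrow(sub)
  structure(list(
    water_mass = label, region = region, tracer = tracer,
    mean_conc = mean_conc,
    sd_conc = if (n > 1L) stats::sd(sub[[tracer]]) else NA_real_,
    mean_sal = mean_sal, n = n,
    stations = sort(unique(sub$station)),
    samples = sub[[tracer]]
  ), class = "pooled_mean")
}

#' @export
print.pooled_mean <- function(x, ...) {
  cat(sprintf(
    "Pooled %s in %s/%s: %.3f umol/kg (sd %.3f, n=%d), S=%.3f, %d station(s)\n",
    x$tracer, x$region, x$water_mass, x$mean_conc,
    ifelse(is.na(x$sd_conc), NA, x$sd_conc), x$n, x$mean_sal,
    length(x$stations)))
  invisible(x)
}
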