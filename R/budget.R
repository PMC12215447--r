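## Nitrogen flux ledger.
##
## Sign convention: positive = nitrogen added to the fjord's water column.
## Sediment burial, denitrification to the atmosphere and removal by birds
## are therefore negative entries. Fluxes derived from observations
## (atmospheric deposition, riverine input, fjord-ocean exchange) are
## computed here; literature-constant fluxes enter as pass-through entries
## with a provenance string.

FLUX_CATEGORIES <- c("atmospheric", "riverine", "ocean_exchange",
                     "biological", "sediment", "internal_transformation")

#' Construct a nitrogen flux ledger entry
#'
#' @param name entry name.
#' @param category one of `"atmospheric"`, `"riverine"`, `"ocean_exchange"`,
#'   `"biological"`, `"sediment"`, `"internal_transformation"`.
#' @param value signed flux, tonnes N d⁻¹ (positive into the water column).
#' @param range_lo,range_hi optional range, must bracket `value`.
#' @param season `"summer"` or `"annual"`.
#' @param provenance free-text origin.
#' @return one-row data.frame of class `flux_entry`.
#' @export
flux_entry <- function(name, category, value, range_lo = NA_real_,
                       range_hi = NA_real_, season = c("summer", "annual"),
                       provenance = "") {
  season <- match.arg(season)
  category <- match.arg(category, FLUX_CATEGORIES)
  stopifnot(is.finite(value))
  if (!is.na(range_lo) && !is.na(range_hi) &&
      !(range_lo <= value && value <= range_hi)) {
    stop("flux range [", range_lo, ", ", range_hi, "] does not bracket value ",
         value, call. = FALSE)
  }
  structure(data.frame(name = name, category = category, value = value,
                       range_lo = range_lo, range_hi = range_hi,
                       season = season, provenance = provenance,
                       stringsAsFactors = FALSE),
            class = c("flux_entry", "data.frame"))
}

#' Bind flux entries into a ledger
#'
#' @param ... `flux_entry` objects or ledgers.
#' @return a `flux_ledger` data.frame.
#' @export
flux_ledger <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- if (length(parts)) do.call(rbind, lapply(parts, as.data.frame)) else
    flux_entry("empty", "biological", 0)[0, ]
  class(out) <- c("flux_ledger", "data.frame")
  out
}

#' Atmospheric nitrogen deposition flux
#'
#' From weekly-scale deposition periods: per period, deposition per unit
#' area (mg N m⁻²) = precipitation (mm) × concentration (mg N L⁻¹), because
#' 1 mm of rain over 1 m² is 1 L. The total deposition over all periods is
#' divided by the number of days covered (the union of the period spans;
#' overlapping periods trigger a warning, not an error), then upscaled to the
#' fjord area.
#'
#' @param periods data.frame with columns `start`, `end` (Dates or coercible),
#'   `precip_mm` (total precipitation in the period) and `conc_mg_l`
#'   (mg N L⁻¹).
#' @param area_km2 fjord area, km².
#' @param season,name,provenance ledger metadata.
#' @return a `flux_entry` in tonnes N d⁻¹ (positive).
#' @examples
#' p <- data.frame(start = as.Date("2020-07-01"), end = as.Date("2020-07-08"),
#'                 precip_mm = 10, conc_mg_l = 0.2)
#' atmospheric_deposition(p, 231.5)$value  # ~0.066
#' @export
atmospheric_deposition <- function(periods, area_km2 = 231.5,
                                   season = "summer",
                                   name = "atmospheric deposition",
                                   provenance = "computed") {
  stopifnot(is.data.frame(periods), nrow(periods) >= 1L, area_km2 > 0,
            all(c("start", "end", "precip_mm", "conc_mg_l") %in%
                  names(periods)))
  start <- as.Date(periods$start)
  end <- as.Date(periods$end)
  if (any(end <= start)) stop("deposition period with end <= start",
                              call. = FALSE)
  if (any(periods$precip_mm < 0) || any(periods$conc_mg_l < 0)) {
    stop("negative precipitation or concentration", call. = FALSE)
  }
  # union of covered days (detects overlap)
  days <- unique(unlist(mapply(function(s, e) seq(s, e - 1, by = "day"),
                               start, end, SIMPLIFY = FALSE)))
  span_days <- length(days)
  total_span <- sum(as.numeric(end - start))
  if (total_span > span_days) {
    warning("overlapping deposition periods; using the union span (",
            span_days, " days)")
  }
  dep_mg_m2 <- sum(periods$precip_mm * periods$conc_mg_l)  # mg N m^-2 total
  daily_mg_m2 <- dep_mg_m2 / span_days
  tonnes_d <- daily_mg_m2 * area_km2 * 1e6 * 1e-9  # mg -> tonnes
  flux_entry(name, "atmospheric", tonnes_d, season = season,
             provenance = provenance)
}

#' Riverine nitrogen flux
#'
#' Product of mean daily runoff and river nitrogen concentration:
#' tonnes N d⁻¹ = (runoff/span, m³ d⁻¹) × conc (µmol L⁻¹ ≡ mmol m⁻³) ×
#' 14.007 g mol⁻¹ × 1e-9.
#'
#' @param runoff_volume total runoff over the span, m³ (≥ 0).
#' @param span span covered, days (> 0).
#' @param conc nitrogen concentration, µmol L⁻¹.
#' @param season,name,provenance ledger metadata.
#' @return a `flux_entry` in tonnes N d⁻¹ (positive).
#' @examples
#' riverine_flux(1e6, 1, 2.0)$value  # 0.028
#' @export
riverine_flux <- function(runoff_volume, span, conc, season = "summer",
                          name = "riverine input", provenance = "computed") {
  stopifnot(span > 0, conc >= 0)
  if (!is.finite(runoff_volume) || runoff_volume < 0) {
    stop("negative runoff volume", call. = FALSE)
  }
  tonnes_d <- (runoff_volume / span) * conc * 14.007 * 1e-9
  flux_entry(name, "riverine", tonnes_d, season = season,
             provenance = provenance)
}

#' Fjord-ocean nitrogen exchange flux
#'
#' Volume transport times DIN concentration:
#' tonnes N d⁻¹ = transport (m³ s⁻¹) × 86400 × DIN (µmol L⁻¹ ≡ mmol m⁻³) ×
#' 14.007 × 1e-9. The sign follows the transport (positive into the fjord).
#'
#' @param transport signed volume transport, m³ s⁻¹.
#' @param din_conc dissolved inorganic nitrogen concentration, µmol L⁻¹ (≥ 0).
#' @param season,name,provenance ledger metadata.
#' @return a `flux_entry` in tonnes N d⁻¹.
#' @examples
#' ocean_exchange_flux(10000, 5)$value  # 60.5
#' @export
ocean_exchange_flux <- function(transport, din_conc, season = "summer",
                                name = "fjord-ocean DIN exchange",
                                provenance = "computed") {
  stopifnot(is.finite(transport), din_conc >= 0)
  tonnes_d <- transport * 86400 * din_conc * 14.007 * 1e-9
  flux_entry(name, "ocean_exchange", tonnes_d, season = season,
             provenance = provenance)
}

#' Internal nitrogen balance of the ledger
#'
#' Signed sum of all entries whose category is not excluded. Excluding ocean
#' exchange (the default) gives the balance of the fjord-internal terms:
#' negative = net loss from the water column.
#'
#' @param entries a `flux_ledger` (or data.frame with `category`, `value`).
#' @param exclude categories to leave out; default `"ocean_exchange"`.
#' @return signed sum, tonnes N d⁻¹.
#' @export
internal_balance <- function(entries, exclude = "ocean_exchange") {
  stopifnot(is.data.frame(entries))
  if (nrow(entries) == 0L) {
    warning("empty ledger; balance is 0")
    return(0)
  }
  keep <- !(entries$category %in% exclude)
  if (!any(keep)) {
    warning("all ledger entries excluded; balance is 0")
    return(0)
  }
  sum(entries$value[keep])
}

#' Format the nitrogen budget ledger
#'
#' Deterministic report: entries grouped by category, ordered by decreasing
#' |value| within category, with per-category subtotals and ranges rendered
#' as `"lo - hi"`.
#'
#' @param entries a `flux_ledger`.
#' @param file path, `""` for stdout, or `NULL` to return lines invisibly.
#' @return the formatted lines, invisibly.
#' @export
budget_report <- function(entries, file = "") {
  stopifnot(is.data.frame(entries))
  lines <- sprintf("%-32s %-24s %10s  %-13s %s",
                   "name", "category", "tonnes_N_d", "range", "season")
  for (cat_ in intersect(FLUX_CATEGORIES, unique(entries$category))) {
    sub <- entries[entries$category == cat_, , drop = FALSE]
    sub <- sub[order(-abs(sub$value)), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      rng <- if (!is.na(sub$range_lo[i]) && !is.na(sub$range_hi[i])) {
        sprintf("%g - %g", sub$range_lo[i], sub$range_hi[i])
      } else ""
      lines <- c(lines, sprintf("%-32s %-24s %10.3f  %-13s %s",
                                sub$name[i], cat_, sub$value[i], rng,
                                sub$season[i]))
    }
    lines <- c(lines, sprintf("%-32s %-24s %10.3f", "  subtotal", cat_,
                              sum(sub$value)))
  }
  if (nrow(entries) > 0L) {
    lines <- c(lines,
               sprintf("%-57s %10.3f", "TOTAL (all categories)",
                       sum(entries$value)),
               sprintf("%-57s %10.3f", "internal balance (excl. ocean exchange)",
                       internal_balance(entries)))
  }
  if (!is.null(file)) writeLines(lines, con = if (identical(file, "")) stdout() else file)
  invisible(lines)
}
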