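## Bottle-table I/O.
##
## A bottle table is a plain data.frame with one row per water sample:
## columns station, region ("fjord", "shelf" or "fram_strait"), year,
## date (optional), depth (m, positive down), temperature (deg C),
## salinity (practical), and one column per tracer in umol kg^-1
## (canonical names: nitrate_nitrite, ammonium, phosphate, silicic_acid,
## dic; free-form extras are carried through). Missing measurements are NA,
## never sentinel numbers.

REGIONS <- c("fjord", "shelf", "fram_strait")
BOTTLE_META <- c("station", "region", "year", "date", "depth",
                 "temperature", "salinity")

#' Read a delimited bottle table
#'
#' Reads CSV/TSV hydrographic bottle data into the package's bottle-table
#' layout, resolving column names through `column_map`, converting tracer
#' concentrations to µmol kg⁻¹, and validating physical invariants
#' (depth ≥ 0, 0 ≤ salinity ≤ 42, concentrations ≥ 0, DIC > 0).
#' Unparseable or empty tracer cells become `NA` (absent), never zero.
#'
#' @param source path or connection to a delimited text file with a header.
#' @param column_map optional named character vector mapping canonical names
#'   (e.g. `c(nitrate_nitrite = "NO3_NO2")`) to the file's column names.
#'   Unmapped canonical columns are matched case-insensitively by name.
#' @param unit unit of the tracer columns in the file: `"umol_per_kg"`
#'   (default, no conversion) or `"umol_per_L"`.
#' @param reference_density density (kg m⁻³) used for µM → µmol kg⁻¹
#'   conversion; default 1000 makes the two units numerically equal.
#' @param sep field separator; `NULL` (default) sniffs comma vs tab from the
#'   header line.
#' @param tracers tracer column names to look for; defaults to the canonical
#'   five plus anything named in `column_map`.
#' @return a bottle-table `data.frame`.
#' @seealso [write_bottle_table()]
#' @export
read_bottle_table <- function(source, column_map = NULL,
                              unit = c("umol_per_kg", "umol_per_L"),
                              reference_density = 1000,
                              sep = NULL, tracers = NULL) {
  unit <- match.arg(unit)
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("file not found: ", source, call. = FALSE)
    first <- readLines(source, n = 1L)
  } else {
    stop("source must be a file path", call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(source, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "\"", na.strings = c("NA", "", "-"))

  tracers <- unique(c(tracers %||% TRACERS,
                      intersect(names(column_map), setdiff(names(column_map), BOTTLE_META))))
  tracers <- setdiff(tolower(tracers), BOTTLE_META)

  resolve <- function(canon) {
    if (!is.null(column_map) && canon %in% names(column_map)) {
      hit <- column_map[[canon]]
      if (!hit %in% names(raw)) {
        stop("column '", hit, "' (mapped to ", canon, ") not found in file",
             call. = FALSE)
      }
      return(hit)
    }
    i <- match(canon, tolower(names(raw)))
    if (is.na(i)) NA_character_ else names(raw)[i]
  }

  required <- c("station", "region", "year", "depth", "salinity")
  cols <- vapply(c(BOTTLE_META, tracers), resolve, character(1))
  missing_req <- required[is.na(cols[required])]
  if (length(missing_req) > 0L) {
    stop("required column(s) missing from bottle table: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    station = raw[[cols["station"]]],
    region = tolower(trimws(raw[[cols["region"]]])),
    year = as.integer(num(raw[[cols["year"]]])),
    depth = num(raw[[cols["depth"]]]),
    salinity = num(raw[[cols["salinity"]]]),
    stringsAsFactors = FALSE
  )
  out$date <- if (!is.na(cols["date"])) as.Date(raw[[cols["date"]]]) else as.Date(NA)
  out$temperature <- if (!is.na(cols["temperature"])) num(raw[[cols["temperature"]]]) else NA_real_
  for (tr in tracers) {
    if (is.na(cols[tr])) next
    v <- num(raw[[cols[tr]]])
    if (unit == "umol_per_L") v <- to_umol_per_kg(v, reference_density)
    out[[tr]] <- v
  }
  out <- out[, c(BOTTLE_META, intersect(tracers, names(out)))]
  validate_bottle_table(out)
  fn_info(nrow(out), " bottle records read from ", source)
  out
}

#' Validate a bottle table against its physical invariants
#'
#' @param df a bottle-table `data.frame`.
#' @return `df`, invisibly; errors name the offending row.
#' @export
validate_bottle_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("station", "region", "year", "depth", "salinity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("bottle table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_region <- which(!df$region %in% REGIONS)
  if (length(bad_region) > 0L) {
    stop("unknown region '", df$region[bad_region[1]], "' at row ",
         bad_region[1], " (expected one of ", paste(REGIONS, collapse = ", "),
         ")", call. = FALSE)
  }
  first_bad <- function(ok, what) {
    i <- which(!ok)
    if (length(i) > 0L) {
      stop(what, " at row ", i[1], call. = FALSE)
    }
  }
  first_bad(is.na(df$depth) | df$depth >= 0, "negative depth")
  first_bad(is.na(df$salinity) | (df$salinity >= 0 & df$salinity <= 42),
            "salinity outside [0, 42]")
  for (tr in setdiff(names(df), c(BOTTLE_META))) {
    if (!is.numeric(df[[tr]])) next
    first_bad(is.na(df[[tr]]) | df[[tr]] >= 0,
              paste0("negative ", tr, " concentration"))
  }
  if ("dic" %in% names(df)) {
    first_bad(is.na(df$dic) | df$dic > 0, "non-positive dic")
  }
  invisible(df)
}

#' Write a bottle table
#'
#' Writes the bottle table as delimited text with full numeric precision
#' (numbers survive a read/write/read round trip to better than 6 significant
#' digits). Missing values are written as empty cells.
#'
#' @param df bottle-table `data.frame`.
#' @param file path or `""` for stdout.
#' @param sep field separator (default tab).
#' @return `file`, invisibly.
#' @export
write_bottle_table <- function(df, file = "", sep = "\t") {
  validate_bottle_table(df)
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "",
                         trimws(formatC(out[[j]], digits = 10, format = "g")))
    }
  }
  utils::write.table(out, file = file, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(file)
}

#' Format a result table for reporting
#'
#' Renders a source/sink table (from [annual_source_sink_table()]) or a NEM
#' table (from [nem_table()]) as delimited text in the conventional layout of
#' published fjord source/sink tables: ΔC rounded to one decimal, missing
#' cells as `"-"`, and significance flagged in a marker column (`*` for
#' contrasts whose water-mass means differ at the chosen alpha).
#'
#' @param rows a `source_sink_table` or `nem_table` data.frame (homogeneous
#'   type; mixing the two is an error).
#' @param file path or `""` for stdout; use `NULL` to return lines invisibly
#'   without printing.
#' @param style `"display"` applies the rounding rules above; `"full"` keeps
#'   full numeric precision (for machine round trips).
#' @param sep field separator (default tab).
#' @return the formatted lines, invisibly.
#' @export
write_result_table <- function(rows, file = "", style = c("display", "full"),
                               sep = "\t") {
  style <- match.arg(style)
  is_ss <- inherits(rows, "source_sink_table")
  is_nem <- inherits(rows, "nem_table")
  if (!is.data.frame(rows) || (!is_ss && !is_nem)) {
    stop("rows must be a source_sink_table or nem_table data.frame ",
         "(homogeneous row type)", call. = FALSE)
  }
  out <- as.data.frame(rows)
  fmt <- function(x, digits) {
    ifelse(is.na(x), "-", formatC(round(x, digits), format = "f", digits = digits))
  }
  if (style == "display") {
    if (is_ss) {
      for (cl in intersect(c("delta_C", "C_obs", "C_cons"), names(out))) {
        out[[cl]] <- fmt(out[[cl]], 1)
      }
      if ("S_obs" %in% names(out)) out$S_obs <- fmt(out$S_obs, 2)
      if ("p_value" %in% names(out)) out$p_value <- fmt(out$p_value, 4)
      if ("significant" %in% names(out)) {
        out$sig <- ifelse(!is.na(out$significant) & out$significant, "*", "")
        out$significant <- NULL
      }
    } else {
      rules <- c(delta_C = 1, rate = 1, integrated_mol = 2, integrated_g = 1)
      for (cl in intersect(names(rules), names(out))) {
        out[[cl]] <- fmt(out[[cl]], rules[[cl]])
      }
      if ("areal_tonnes" %in% names(out)) {
        out$areal_tonnes <- ifelse(is.na(out$areal_tonnes), "-",
                                   formatC(round(out$areal_tonnes), format = "d"))
      }
    }
  }
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "-",
                         trimws(formatC(out[[j]], digits = 10, format = "g")))
    } else if (is.logical(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "-", ifelse(out[[j]], "TRUE", "FALSE"))
    } else {
      out[[j]][is.na(out[[j]])] <- "-"
    }
  }
  lines <- c(paste(names(out), collapse = sep),
             do.call(paste, c(unname(as.list(out)), sep = sep)))
  if (!is.null(file)) writeLines(lines, con = if (identical(file, "")) stdout() else file)
  invisible(lines)
}
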