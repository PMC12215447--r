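#' Concentration unit conversion between per-kilogram and per-litre
#'
#' Bottle nutrient data are reported either per mass of seawater
#' (µmol kg⁻¹) or per volume (µmol L⁻¹, "µM"). Conversion uses a single
#' nominal reference density rather than per-sample in-situ density: with the
#' default 1000 kg m⁻³ the two units are numerically identical, which is how
#' gram-unit NEM results are conventionally reported; a realistic seawater
#' density (~1025) changes values by ~2.5%.
#'
#' @param x numeric vector of concentrations.
#' @param reference_density reference density in kg m⁻³, within \[990, 1035\].
#' @return numeric vector in the target unit.
#' @examples
#' to_umol_per_kg(2.05, reference_density = 1025)  # 2.0
#' @export
to_umol_per_kg <- function(x, reference_density = 1000) {
  check_reference_density(reference_density)
  x / (reference_density / 1000)
}

#' @rdname to_umol_per_kg
#' @export
to_umol_per_L <- function(x, reference_density = 1000) {
  check_reference_density(reference_density)
  x * (reference_density / 1000)
}

check_reference_density <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) ||
      rho < 990 || rho > 1035) {
    stop("reference_density must be a single value in [990, 1035] kg m^-3",
         call. = FALSE)
  }
  invisible(rho)
}
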