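#' Convert a quantity to SI units
#'
#' All internal computation in mcdtsim is carried out in a single SI system
#' (m, s, Pa, mol m^-3, T, A m^-1). Parameter tables in the tumor-transport
#' literature mix molar concentrations, cm-based diffusivities and mmHg
#' pressures; this helper performs the exact conversion once, at the input
#' boundary.
#'
#' Supported unit tokens (case-sensitive):
#' \describe{
#'   \item{concentration}{`"M"` (mol/L), `"mM"`, `"uM"`, `"mol/m^3"`}
#'   \item{diffusivity}{`"cm^2/s"`, `"m^2/s"`}
#'   \item{speed / permeability}{`"cm/s"`, `"um/s"`, `"m/s"`}
#'   \item{pressure}{`"Pa"`, `"kPa"`, `"mmHg"`}
#'   \item{flux density}{`"T"`, `"mT"`}
#'   \item{length}{`"nm"`, `"um"`, `"mm"`, `"cm"`, `"m"`}
#'   \item{time / rate}{`"s"`, `"min"`, `"h"`, `"1/s"`}
#'   \item{binding rate}{`"1/M/s"` (per molar per second), `"m^3/mol/s"`}
#'   \item{viscosity}{`"Pa.s"`}
#'   \item{dimensionless}{`"-"` or `""`}
#' }
#'
#' @param value numeric vector, the quantity in the unit given by `unit`.
#' @param unit character scalar, one of the supported unit tokens.
#' @return numeric vector in the SI base combination of the same dimension.
#' @examples
#' normalize_units(1.5e2, "1/M/s")    # 0.15 m^3 mol^-1 s^-1
#' normalize_units(3.40e-6, "cm^2/s") # 3.40e-10 m^2/s
#' normalize_units(1e-5, "M")         # 1e-2 mol/m^3
#' @export
normalize_units <- function(value, unit) {
  stopifnot(is.numeric(value), is.character(unit), length(unit) == 1L)
  if (!nzchar(unit)) return(value)  # no unit token: already dimensionless/SI
  factor <- switch(unit,
    # concentration: 1 M = 1 mol/L = 1e3 mol/m^3
    "M"        = 1e3,
    "mM"       = 1,
    "uM"       = 1e-3,
    "mol/m^3"  = 1,
    # diffusivity
    "cm^2/s"   = 1e-4,
    "m^2/s"    = 1,
    # speed / permeability coefficient
    "cm/s"     = 1e-2,
    "um/s"     = 1e-6,
    "m/s"      = 1,
    # pressure
    "Pa"       = 1,
    "kPa"      = 1e3,
    "mmHg"     = 133.322387415,
    # magnetic flux density
    "T"        = 1,
    "mT"       = 1e-3,
    # length
    "nm"       = 1e-9,
    "um"       = 1e-6,
    "mm"       = 1e-3,
    "cm"       = 1e-2,
    "m"        = 1,
    # time and first-order rates
    "s"        = 1,
    "min"      = 60,
    "h"        = 3600,
    "1/s"      = 1,
    # second-order binding rate: 1 M^-1 s^-1 = 1e-3 m^3 mol^-1 s^-1
    "1/M/s"    = 1e-3,
    "m^3/mol/s" = 1,
    # viscosity
    "Pa.s"     = 1,
    # dimensionless
    "-"        = 1,
    stop("normalize_units(): unknown unit token '", unit, "'", call. = FALSE)
  )
  value * factor
}
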