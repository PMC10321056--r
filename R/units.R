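#' Physical constants and unit conversions
#'
#' Internal units throughout the package are kcal mol^-1, Angstrom, ps and K.
#' `gas_constant()` returns R in kcal mol^-1 K^-1; `thermal_energy()` returns
#' RT at a given temperature.
#'
#' @param temperature temperature in K.
#' @return `gas_constant()`: R in kcal mol^-1 K^-1; `thermal_energy()`: RT in
#'   kcal mol^-1.
#' @examples
#' thermal_energy(298.15)  # ~0.5925 kcal/mol
#' @export
gas_constant <- function() 1.98720425e-3

#' @rdname gas_constant
#' @export
thermal_energy <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), temperature > 0)
  gas_constant() * temperature
}

#' Default simulation temperature (K)
#' @export
default_temperature <- function() 298.15

# Coulomb prefactor for q in elementary charges, r in Angstrom,
# energy in kcal/mol (vacuum permittivity).
coulomb_constant <- function() 332.0637

#' Convert a harmonic force constant between unit systems
#'
#' Umbrella-sampling protocols mix `kJ/mol/nm^2` (GROMACS convention) and
#' `kcal/mol/A^2` (Tinker convention).  The exact conversion factor is
#' 418.4 = 4.184 (kJ per kcal) x 100 (A^2 per nm^2).
#'
#' @param value numeric force constant(s).
#' @param from,to unit strings, one of `"kJ/mol/nm^2"` or `"kcal/mol/A^2"`.
#' @return the converted value; round-tripping is exact.
#' @examples
#' convert_force_constant(500, "kJ/mol/nm^2", "kcal/mol/A^2")  # 1.195
#' @export
convert_force_constant <- function(value, from, to) {
  norm <- function(u) {
    u <- gsub("\\s+", "", tolower(u))
    u <- gsub("Å|å|ang(strom)?", "a", u)
    if (u %in% c("kj/mol/nm^2", "kj/mol/nm2", "kjmol-1nm-2")) return("kj_nm")
    if (u %in% c("kcal/mol/a^2", "kcal/mol/a2", "kcalmol-1a-2")) return("kcal_a")
    stop("unknown force-constant unit: '", u,
         "' (expected kJ/mol/nm^2 or kcal/mol/A^2)", call. = FALSE)
  }
  f <- norm(from); t <- norm(to)
  if (f == t) return(value)
  if (f == "kj_nm") value / 418.4 else value * 418.4
}
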