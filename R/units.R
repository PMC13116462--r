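# Unit conversions between SI and the micro-units used when reporting
# thresholds (uW/mm3, uJ/mm3). Internally everything is SI; these helpers
# exist only at I/O boundaries.

.power_density_si <- c("W/m3" = 1, "uW/mm3" = 1e3)
.energy_density_si <- c("J/m3" = 1, "J/mm3" = 1e9, "uJ/mm3" = 1e3)

.unit_factor <- function(unit, table, what) {
  # tolerate the unicode mu spelling
  unit <- gsub("µ|μ", "u", unit)
  unit <- gsub("\\^", "", unit)
  if (!unit %in% names(table)) {
    stop("unknown ", what, " unit: `", unit, "` (expected one of ",
         paste(names(table), collapse = ", "), ")", call. = FALSE)
  }
  table[[unit]]
}

#' Convert a power density between unit systems
#'
#' Supported units: `"W/m3"` and `"uW/mm3"` (1 uW/mm3 = 1000 W/m3). The
#' micro sign may be written `u` or the unicode mu.
#'
#' @param value Numeric vector of power densities.
#' @param from,to Unit names.
#' @return `value` expressed in `to` units.
#' @export
#' @examples
#' convert_power_density(7, "uW/mm3", "W/m3")  # 7000
convert_power_density <- function(value, from, to) {
  value * .unit_factor(from, .power_density_si, "power-density") /
    .unit_factor(to, .power_density_si, "power-density")
}

#' Convert an energy density between unit systems
#'
#' Supported units: `"J/m3"`, `"J/mm3"` and `"uJ/mm3"`
#' (1 uJ/mm3 = 1000 J/m3; 1 J/mm3 = 1e9 J/m3).
#'
#' @inheritParams convert_power_density
#' @return `value` expressed in `to` units.
#' @export
#' @examples
#' convert_energy_density(5.9e5, "J/m3", "J/mm3")  # 5.9e-4
convert_energy_density <- function(value, from, to) {
  value * .unit_factor(from, .energy_density_si, "energy-density") /
    .unit_factor(to, .energy_density_si, "energy-density")
}
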