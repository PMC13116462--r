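#' Well geometry configuration
#'
#' Describes the treated well: its radius, the electrode gap above the liquid
#' surface, and the heights of the stacked layers the current traverses
#' (buffer, cell layer, dish bottom) plus the plasma-membrane thickness.
#' All arguments are in SI units (metres); defaults describe a 96-well plate
#' with a 6.4 mm well diameter.
#'
#' @param well_radius Well radius in m (default 3.2e-3, i.e. 6.4 mm diameter).
#' @param electrode_gap Needle-to-surface gap in m (informational; 0.5 mm).
#' @param buffer_height Height of the buffer droplet layer Hs in m (0.1 mm).
#' @param cell_height Height of the cell layer Hc in m (10 um).
#' @param membrane_thickness Plasma-membrane thickness Tm in m (7.5 nm).
#' @param dish_height Dish-bottom thickness Hd in m (1.5 mm).
#'
#' @return An object of class `geometry_config` (a named list).
#' @export
#' @examples
#' geometry_config()
geometry_config <- function(well_radius = 3.2e-3,
                            electrode_gap = 0.5e-3,
                            buffer_height = 0.1e-3,
                            cell_height = 10e-6,
                            membrane_thickness = 7.5e-9,
                            dish_height = 1.5e-3) {
  g <- list(
    well_radius = well_radius,
    electrode_gap = electrode_gap,
    buffer_height = buffer_height,
    cell_height = cell_height,
    membrane_thickness = membrane_thickness,
    dish_height = dish_height
  )
  for (key in names(g)) {
    v <- g[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("geometry_config: `", key, "` must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (g$membrane_thickness >= g$cell_height) {
    stop("geometry_config: `membrane_thickness` must be smaller than `cell_height`",
         call. = FALSE)
  }
  structure(g, class = "geometry_config")
}

#' Material (electrical) properties of the layers
#'
#' Electrical constants for the buffer, cytoplasm, membrane and dish.
#' Relative permittivities are multiplied by the vacuum permittivity
#' internally. The membrane relative permittivity is not pinned down by the
#' layer table the defaults come from; 5 (a typical lipid-bilayer value,
#' range roughly 2-7) is an explicit, configurable default, so fitted
#' thresholds must be read as effective parameters.
#'
#' @param cytoplasm_rel_permittivity Relative permittivity of cytoplasm (30).
#' @param cytoplasm_conductivity Cytoplasm conductivity in S/m (1).
#' @param buffer_conductivity Buffer (PBS + DNA droplet) conductivity in
#'   S/m (0.172).
#' @param dish_rel_permittivity Relative permittivity of the dish bottom (2.4).
#' @param membrane_rel_permittivity Relative permittivity of the plasma
#'   membrane (default 5; see Details).
#' @param membrane_conductivity Membrane conductivity in S/m (default 0, an
#'   intact membrane is treated as an ideal dielectric).
#'
#' @return An object of class `material_config`. Absolute permittivities are
#'   available as `cytoplasm_permittivity`, `dish_permittivity` and
#'   `membrane_permittivity` (F/m).
#' @export
material_config <- function(cytoplasm_rel_permittivity = 30,
                            cytoplasm_conductivity = 1,
                            buffer_conductivity = 0.172,
                            dish_rel_permittivity = 2.4,
                            membrane_rel_permittivity = 5,
                            membrane_conductivity = 0) {
  rels <- c(cytoplasm_rel_permittivity, dish_rel_permittivity,
            membrane_rel_permittivity)
  if (any(!is.finite(rels)) || any(rels <= 0)) {
    stop("material_config: permittivities must be positive", call. = FALSE)
  }
  conds <- c(cytoplasm_conductivity, buffer_conductivity, membrane_conductivity)
  if (any(!is.finite(conds)) || any(conds < 0)) {
    stop("material_config: conductivities must be non-negative", call. = FALSE)
  }
  structure(list(
    vacuum_permittivity = vacuum_permittivity(),
    cytoplasm_rel_permittivity = cytoplasm_rel_permittivity,
    cytoplasm_permittivity = cytoplasm_rel_permittivity * vacuum_permittivity(),
    cytoplasm_conductivity = cytoplasm_conductivity,
    buffer_conductivity = buffer_conductivity,
    dish_rel_permittivity = dish_rel_permittivity,
    dish_permittivity = dish_rel_permittivity * vacuum_permittivity(),
    membrane_rel_permittivity = membrane_rel_permittivity,
    membrane_permittivity = membrane_rel_permittivity * vacuum_permittivity(),
    membrane_conductivity = membrane_conductivity
  ), class = "material_config")
}

#' Vacuum permittivity (F/m)
#' @return The electric constant, 8.8541878128e-12 F/m.
#' @export
vacuum_permittivity <- function() 8.8541878128e-12

#' Sinusoidal drive configuration
#'
#' The high-voltage sinusoidal drive applied through the plasma channel:
#' `v(t) = amplitude * sin(2 * pi * frequency * t + phase)`, with the
#' amplitude defined as half the peak-to-peak voltage. Default: 20 kHz,
#' 20 kV peak-to-peak, phase 0 at treatment onset.
#'
#' @param frequency Drive frequency in Hz (default 20e3).
#' @param peak_to_peak_voltage Peak-to-peak voltage in V (default 20e3).
#' @param phase Phase at t = 0 in radians (default 0).
#'
#' @return An object of class `drive_config` with the derived `amplitude`.
#' @export
drive_config <- function(frequency = 20e3,
                         peak_to_peak_voltage = 20e3,
                         phase = 0) {
  if (!is.finite(frequency) || frequency <= 0) {
    stop("drive_config: `frequency` must be positive", call. = FALSE)
  }
  if (!is.finite(peak_to_peak_voltage) || peak_to_peak_voltage < 0) {
    stop("drive_config: `peak_to_peak_voltage` must be non-negative", call. = FALSE)
  }
  structure(list(
    frequency = frequency,
    peak_to_peak_voltage = peak_to_peak_voltage,
    amplitude = peak_to_peak_voltage / 2,
    phase = phase
  ), class = "drive_config")
}

#' Default full configuration
#'
#' Bundles the default geometry, materials and drive into one list, the
#' configuration used throughout the package's examples and tests.
#'
#' @return A list with elements `geometry`, `materials`, `drive`.
#' @export
default_config <- function() {
  list(geometry = geometry_config(),
       materials = material_config(),
       drive = drive_config())
}

# Keys accepted in a YAML config file, with the unit scale (file unit -> SI)
# and the constructor argument each maps to.
.config_keys <- list(
  geometry = list(
    well_diameter_mm  = list(arg = "well_radius", scale = 1e-3 / 2),
    well_radius_mm    = list(arg = "well_radius", scale = 1e-3),
    electrode_gap_mm  = list(arg = "electrode_gap", scale = 1e-3),
    buffer_height_mm  = list(arg = "buffer_height", scale = 1e-3),
    cell_height_um    = list(arg = "cell_height", scale = 1e-6),
    membrane_thickness_nm = list(arg = "membrane_thickness", scale = 1e-9),
    dish_height_mm    = list(arg = "dish_height", scale = 1e-3)
  ),
  materials = list(
    cytoplasm_rel_permittivity = list(arg = "cytoplasm_rel_permittivity", scale = 1),
    cytoplasm_conductivity_S_m = list(arg = "cytoplasm_conductivity", scale = 1),
    buffer_conductivity_S_m    = list(arg = "buffer_conductivity", scale = 1),
    dish_rel_permittivity      = list(arg = "dish_rel_permittivity", scale = 1),
    membrane_rel_permittivity  = list(arg = "membrane_rel_permittivity", scale = 1),
    membrane_conductivity_S_m  = list(arg = "membrane_conductivity", scale = 1)
  ),
  drive = list(
    frequency_kHz = list(arg = "frequency", scale = 1e3),
    peak_to_peak_kV = list(arg = "peak_to_peak_voltage", scale = 1e3),
    phase_rad = list(arg = "phase", scale = 1)
  )
)

#' Load a configuration file
#'
#' Reads a YAML document with up to three sections (`geometry`, `materials`,
#' `drive`). Every key is optional; missing keys fall back to the package
#' defaults. Keys use the reporting units conventional for this system
#' (mm, um, nm, kHz, kV peak-to-peak, S/m); values are converted to SI on
#' load. Unknown keys and out-of-range values are rejected with the
#' offending key named.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `geometry`, `materials`, `drive`, as from
#'   [default_config()].
#' @export
load_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("load_config: malformed config document", call. = FALSE)
  unknown_sections <- setdiff(names(doc), names(.config_keys))
  if (length(unknown_sections) > 0) {
    stop("load_config: unknown section(s): ",
         paste(unknown_sections, collapse = ", "), call. = FALSE)
  }
  build <- function(section, ctor) {
    keys <- .config_keys[[section]]
    given <- doc[[section]]
    if (is.null(given)) given <- list()
    unknown <- setdiff(names(given), names(keys))
    if (length(unknown) > 0) {
      stop("load_config: unknown key(s) in `", section, "`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    args <- list()
    for (key in names(given)) {
      v <- given[[key]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        stop("load_config: key `", key, "` must be a single finite number",
             call. = FALSE)
      }
      args[[keys[[key]]$arg]] <- v * keys[[key]]$scale
    }
    tryCatch(do.call(ctor, args), error = function(e) {
      stop("load_config: invalid value in `", section, "`: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  list(geometry = build("geometry", geometry_config),
       materials = build("materials", material_config),
       drive = build("drive", drive_config))
}

#' @export
print.geometry_config <- function(x, ...) {
  cat("<geometry_config>\n")
  cat(sprintf("  well radius      %g mm\n", x$well_radius * 1e3))
  cat(sprintf("  buffer height    %g mm\n", x$buffer_height * 1e3))
  cat(sprintf("  cell height      %g um\n", x$cell_height * 1e6))
  cat(sprintf("  membrane         %g nm\n", x$membrane_thickness * 1e9))
  cat(sprintf("  dish height      %g mm\n", x$dish_height * 1e3))
  invisible(x)
}

#' @export
print.drive_config <- function(x, ...) {
  cat("<drive_config>\n")
  cat(sprintf("  %g kHz, %g kVpp (amplitude %g kV), phase %g rad\n",
              x$frequency / 1e3, x$peak_to_peak_voltage / 1e3,
              x$amplitude / 1e3, x$phase))
  invisible(x)
}
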