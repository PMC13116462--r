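# Dose field: cytoplasm current densities and the derived power/energy
# densities. The current density J driving cell damage is the magnitude of
# the combined radial and vertical components of the current flowing through
# the cytoplasm layer; the instantaneous power density is p = J^2 / sigma
# with sigma the cytoplasm conductivity, and the injected energy density is
# the time integral of p over the treatment duration.

#' Per-region cytoplasm current-density phasors
#'
#' The vertical component of region `n` is the total vertical cytoplasm
#' branch current (resistive plus capacitive) divided by the region's
#' annulus area. The radial component is the mean of the current densities
#' at the region's two cylindrical boundaries, each the radial cytoplasm
#' link current divided by its lateral area `2 pi r_boundary Hc`; the axis
#' (inner boundary of region 1) and the wall (outer boundary of region 40)
#' carry no radial current.
#'
#' @param solution A [solve_phasor()] solution of the assembled EECN.
#' @param mesh The [build_mesh()] mesh.
#' @param network The [assemble_network()] network that was solved.
#' @param materials The [material_config()] used (for the cytoplasm
#'   conductivity entering `p = J^2 / sigma`).
#' @return A tibble of class `dose_field` with per-region columns `region`,
#'   `center_radius` (m), `Jr`, `Jz` (complex phasors, A/m2), `J_amp`
#'   (peak combined magnitude, A/m2), `pbar` (cycle-averaged power density,
#'   W/m3) and `p_peak` (peak instantaneous power density, W/m3).
#'   Attributes: `sigma` (S/m), `frequency` (Hz), `phase` (rad).
#' @export
cytoplasm_current_density <- function(solution, mesh, network,
                                      materials = material_config()) {
  if (!inherits(solution, "phasor_solution")) {
    stop("cytoplasm_current_density: `solution` must be a phasor_solution",
         call. = FALSE)
  }
  br <- solution$branches
  n_reg <- nrow(mesh)
  i_of <- function(labels) {
    pos <- match(labels, br$label)
    if (anyNA(pos)) {
      stop("cytoplasm_current_density: missing cytoplasm branch(es): ",
           paste(labels[is.na(pos)], collapse = ", "), call. = FALSE)
    }
    br$current[pos]
  }
  iz <- i_of(paste0("Rcytv", mesh$region)) + i_of(paste0("Ccytv", mesh$region))
  Jz <- iz / mesh$annulus_area
  hc <- network$cell_height
  ir <- i_of(paste0("Rcytr", seq_len(n_reg - 1)))
  jr_boundary <- ir / (2 * pi * network$boundary_radius * hc)
  jr_in <- c(0 + 0i, jr_boundary)   # inner boundary density per region
  jr_out <- c(jr_boundary, 0 + 0i)  # outer boundary density per region
  Jr <- (jr_in + jr_out) / 2
  sigma <- materials$cytoplasm_conductivity
  field <- tibble::tibble(
    region = mesh$region,
    center_radius = mesh$center_radius,
    Jr = Jr,
    Jz = Jz,
    J_amp = sqrt(Mod(Jr)^2 + Mod(Jz)^2),
    pbar = (Mod(Jr)^2 + Mod(Jz)^2) / (2 * sigma),
    p_peak = .peak_power(Mod(Jr), Arg(Jr), Mod(Jz), Arg(Jz), sigma)
  )
  structure(field,
            class = c("dose_field", class(field)),
            sigma = sigma,
            frequency = solution$frequency,
            phase = 0)
}

# Peak over a cycle of p(t) = (a^2 sin^2(wt+pa) + b^2 sin^2(wt+pb)) / sigma.
# Using sin^2 x = (1 - cos 2x)/2 the waveform is mean - 0.5*|a^2 e^{2i pa} +
# b^2 e^{2i pb}| cos(...) so the peak has closed form.
.peak_power <- function(a, pa, b, pb, sigma) {
  mean_term <- (a^2 + b^2) / 2
  osc <- 0.5 * Mod(a^2 * exp(2i * pa) + b^2 * exp(2i * pb))
  (mean_term + osc) / sigma
}

# One steady-state cycle of the instantaneous power density for all regions.
# Returns a list: P (regions x (spc+1) matrix of p samples, W/m3), t (sample
# times), dt, period. Sample k sits at t_k = k / (f * spc), k = 0..spc.
.power_cycle <- function(field, samples_per_cycle = 1024L) {
  f <- attr(field, "frequency")
  sigma <- attr(field, "sigma")
  spc <- as.integer(samples_per_cycle)
  period <- 1 / f
  t <- period * (0:spc) / spc
  wt <- 2 * pi * f * t
  ar <- Mod(field$Jr); pr <- Arg(field$Jr)
  az <- Mod(field$Jz); pz <- Arg(field$Jz)
  Sr <- outer(pr, wt, function(ph, w) sin(w + ph))
  Sz <- outer(pz, wt, function(ph, w) sin(w + ph))
  P <- ((ar * Sr)^2 + (az * Sz)^2) / sigma
  list(P = P, t = t, dt = period / spc, period = period)
}

#' Sampled instantaneous power-density waveform of one region
#'
#' Reconstructs `p(t) = J(t)^2 / sigma` over one steady-state drive cycle
#' from the region's current-density phasors. The waveform is non-negative
#' and periodic at twice the drive frequency; its gating against the power
#' threshold is what distinguishes the Two-Step death model.
#'
#' @param field A [cytoplasm_current_density()] dose field.
#' @param n Region index.
#' @param samples_per_cycle Samples per drive cycle (>= 64; default 1024).
#' @return A tibble with `time` (s, one cycle, inclusive endpoints) and
#'   `p` (W/m3).
#' @export
instantaneous_power_waveform <- function(field, n, samples_per_cycle = 1024L) {
  if (samples_per_cycle < 64) {
    stop("instantaneous_power_waveform: need samples_per_cycle >= 64",
         call. = FALSE)
  }
  if (attr(field, "sigma") <= 0) {
    stop("instantaneous_power_waveform: sigma must be positive", call. = FALSE)
  }
  cyc <- .power_cycle(field, samples_per_cycle)
  i <- match(n, field$region)
  if (is.na(i)) stop("instantaneous_power_waveform: no region ", n, call. = FALSE)
  tibble::tibble(time = cyc$t, p = cyc$P[i, ])
}

#' Injected energy density of one region after a treatment duration
#'
#' Trapezoidal integral of the sampled instantaneous power density from 0 to
#' `tp`, handling the final partial cycle. This is the dose the One-Step
#' death model thresholds.
#'
#' @param field A dose field.
#' @param n Region index.
#' @param tp Treatment duration (s).
#' @param samples_per_cycle Samples per drive cycle (default 1024).
#' @return Energy density in J/m3.
#' @export
injected_energy <- function(field, n, tp, samples_per_cycle = 1024L) {
  if (tp < 0) stop("injected_energy: `tp` must be >= 0", call. = FALSE)
  if (tp == 0) return(0)
  cyc <- .power_cycle(field, samples_per_cycle)
  i <- match(n, field$region)
  if (is.na(i)) stop("injected_energy: no region ", n, call. = FALSE)
  p <- cyc$P[i, ]
  cum <- .cycle_cumtrapz(p, cyc$dt)
  e_cycle <- cum[length(cum)]
  n_full <- floor(tp / cyc$period)
  remainder <- tp - n_full * cyc$period
  # partial cycle: interpolate the within-cycle cumulative integral
  e_part <- stats::approx(cyc$t, cum, xout = remainder, rule = 2)$y
  n_full * e_cycle + e_part
}

# cumulative trapezoid over samples with uniform spacing dt, starting at 0
.cycle_cumtrapz <- function(p, dt) {
  c(0, cumsum((p[-length(p)] + p[-1]) / 2 * dt))
}

#' Write a dose field as CSV (reporting units)
#'
#' Columns: region, center_radius_mm, Jr_amp, Jr_phase, Jz_amp, Jz_phase,
#' pbar_W_per_m3. This file is the input contract for the death-model and
#' fitting stages.
#'
#' @param field A `dose_field`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dose_csv <- function(field, path) {
  out <- tibble::tibble(
    region = field$region,
    center_radius_mm = field$center_radius * 1e3,
    Jr_amp = Mod(field$Jr),
    Jr_phase = Arg(field$Jr),
    Jz_amp = Mod(field$Jz),
    Jz_phase = Arg(field$Jz),
    pbar_W_per_m3 = field$pbar
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a dose field from CSV
#'
#' Inverse of [write_dose_csv()]. The cytoplasm conductivity and drive
#' frequency are not stored in the CSV and must be supplied.
#'
#' @param path CSV path.
#' @param sigma Cytoplasm conductivity (S/m, default 1).
#' @param frequency Drive frequency (Hz, default 20e3).
#' @return A `dose_field` tibble.
#' @export
read_dose_csv <- function(path, sigma = 1, frequency = 20e3) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  Jr <- raw$Jr_amp * exp(1i * raw$Jr_phase)
  Jz <- raw$Jz_amp * exp(1i * raw$Jz_phase)
  field <- tibble::tibble(
    region = raw$region,
    center_radius = raw$center_radius_mm / 1e3,
    Jr = Jr, Jz = Jz,
    J_amp = sqrt(Mod(Jr)^2 + Mod(Jz)^2),
    pbar = (Mod(Jr)^2 + Mod(Jz)^2) / (2 * sigma),
    p_peak = .peak_power(Mod(Jr), Arg(Jr), Mod(Jz), Arg(Jz), sigma)
  )
  structure(field, class = c("dose_field", class(field)),
            sigma = sigma, frequency = frequency, phase = 0)
}

#' Solve the default pipeline up to the dose field
#'
#' Convenience wrapper running mesh construction, element computation,
#' network assembly, the phasor solve and the current-density extraction in
#' one call.
#'
#' @param config A configuration list as from [default_config()] or
#'   [load_config()].
#' @return A list with `mesh`, `network`, `solution`, `field`.
#' @export
#' @examples
#' \donttest{
#' pip <- plasma_dose_field()
#' pip$field
#' }
plasma_dose_field <- function(config = default_config()) {
  mesh <- build_mesh(config$geometry)
  els <- element_values(mesh, config$geometry, config$materials)
  net <- assemble_network(els, mesh, config$drive)
  sol <- solve_phasor(net, config$drive)
  field <- cytoplasm_current_density(sol, mesh, net, config$materials)
  list(mesh = mesh, network = net, solution = sol, field = field)
}
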