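# Threshold-based cell-death models.
#
# One-Step: a cell at radius r dies at the first time t where the injected
# energy density w(r, t) = integral of p(r, t') dt' reaches Wth.
#
# Two-Step: energy accumulates only while the instantaneous power density
# exceeds the power threshold Pth (Heaviside gate, with H(0) = 1), and death
# occurs when this gated accumulation reaches Wth. With Pth = 0 the gate is
# always open and the Two-Step model reduces exactly to the One-Step model.
#
# All accumulation operates on the sampled instantaneous waveform of the
# steady-state cycle; because p(r, t) is periodic, the crossing time is
# computed from per-cycle cumulative profiles, which is exact for the
# sampled waveform and fast enough for grid-search fitting.

#' Death-model parameters
#'
#' Thresholds are given in the reporting units conventional for this system
#' (`pth` in uW/mm3, `wth` in uJ/mm3) and converted to SI internally. A
#' `model = "one_step"` parameter set forces `pth = 0`, making the reduction
#' identity explicit in the representation.
#'
#' @param pth Instantaneous power-density threshold, uW/mm3 (>= 0).
#' @param wth Cumulative energy-density threshold, uJ/mm3 (> 0).
#' @param model `"two_step"` (default) or `"one_step"`.
#' @return An object of class `death_model`, with SI fields `pth_si` (W/m3)
#'   and `wth_si` (J/m3).
#' @export
#' @examples
#' death_model(pth = 7, wth = 0.3)           # the Two-Step best fit
#' death_model(wth = 0.3, model = "one_step")
death_model <- function(pth = 0, wth, model = c("two_step", "one_step")) {
  model <- match.arg(model)
  if (model == "one_step") pth <- 0
  if (!is.finite(pth) || pth < 0) {
    stop("death_model: `pth` must be >= 0", call. = FALSE)
  }
  if (!is.finite(wth) || wth <= 0) {
    stop("death_model: `wth` must be > 0", call. = FALSE)
  }
  structure(list(
    pth = pth, wth = wth, model = model,
    pth_si = convert_power_density(pth, "uW/mm3", "W/m3"),
    wth_si = convert_energy_density(wth, "uJ/mm3", "J/m3")
  ), class = "death_model")
}

#' @export
print.death_model <- function(x, ...) {
  cat(sprintf("<death_model> %s: Pth = %g uW/mm3, Wth = %g uJ/mm3\n",
              x$model, x$pth, x$wth))
  invisible(x)
}

# Gated per-cycle accumulation: given the cycle sample matrix from
# .power_cycle() and an SI power threshold, return the within-cycle
# cumulative gated energy (regions x (spc+1)) and the per-cycle total.
# The Heaviside gate uses H(0) = 1: samples exactly at the threshold count.
.gated_cycle <- function(cycle, pth_si) {
  G <- cycle$P * (cycle$P >= pth_si)
  spc1 <- ncol(G)
  inc <- (G[, -spc1, drop = FALSE] + G[, -1, drop = FALSE]) / 2 * cycle$dt
  cum <- cbind(0, t(apply(inc, 1, cumsum)))
  list(cum = cum, e_cycle = cum[, spc1], t = cycle$t, period = cycle$period)
}

# Time for each region's gated accumulation to reach wth_si (seconds; Inf if
# the gate never opens). Exact for the sampled waveform: whole cycles plus a
# linear interpolation within the crossing interval.
.tstar_from_gated <- function(gc, wth_si) {
  n_reg <- nrow(gc$cum)
  out <- rep(Inf, n_reg)
  live <- which(gc$e_cycle > 0)
  for (i in live) {
    m <- ceiling(wth_si / gc$e_cycle[i]) - 1
    target <- wth_si - m * gc$e_cycle[i]
    cum <- gc$cum[i, ]
    j <- which(cum >= target)[1]
    # the within-cycle target equals the cycle total up to rounding; land on
    # the cycle end rather than missing by one ulp
    if (is.na(j)) j <- length(cum)
    tau <- if (j == 1L) 0 else {
      gc$t[j - 1] + (target - cum[j - 1]) / (cum[j] - cum[j - 1]) *
        (gc$t[j] - gc$t[j - 1])
    }
    out[i] <- m * gc$period + tau
  }
  out
}

#' Time to death of one region
#'
#' Returns the first time at which the (gated) accumulated energy density of
#' region `n` reaches the model's `wth`, or `NA` if the threshold is not
#' reached within `tp_max` (a censored outcome, e.g. when the gate never
#' opens because the peak power stays below `pth`).
#'
#' @param field A [cytoplasm_current_density()] dose field.
#' @param n Region index (vectorised).
#' @param params A [death_model()].
#' @param tp_max Maximum treatment duration considered (s).
#' @param samples_per_cycle Samples per drive cycle (default 1024).
#' @return Time(s) to death in seconds, `NA` where censored.
#' @export
time_to_death <- function(field, n, params, tp_max,
                          samples_per_cycle = 1024L) {
  stopifnot(inherits(params, "death_model"))
  if (tp_max <= 0) stop("time_to_death: `tp_max` must be > 0", call. = FALSE)
  cyc <- .power_cycle(field, samples_per_cycle)
  gc <- .gated_cycle(cyc, params$pth_si)
  tstar <- .tstar_from_gated(gc, params$wth_si)
  idx <- match(n, field$region)
  if (anyNA(idx)) stop("time_to_death: unknown region index", call. = FALSE)
  res <- tstar[idx]
  res[res > tp_max] <- NA_real_
  res
}

# Death radius from a per-region time-to-death profile. cr = center radii,
# R = well radius. The front is the outermost region whose time-to-death is
# within tp; every region inside the front must also be dead (the model
# predicts a dead disc), otherwise the geometric premise is violated and we
# refuse to report a radius. Interpolation: linear in (center_radius, T*)
# between the bracketing regions; "nearest" snaps to the last dead region's
# centre.
.radius_from_tstar <- function(tstar, cr, R, tp,
                               interpolation = c("linear", "nearest"),
                               allow_core_gap = FALSE) {
  interpolation <- match.arg(interpolation)
  n_reg <- length(tstar)
  dead <- tstar <= tp
  if (!any(dead)) {
    return(list(radius = 0, saturated = FALSE, censored = TRUE))
  }
  k <- max(which(dead))
  if (!allow_core_gap && !all(dead[1:k])) {
    stop("death radius: dead regions do not form a disc (time-to-death is ",
         "non-monotone at the death front); the dose field violates the ",
         "model's geometric premise", call. = FALSE)
  }
  if (all(dead)) {
    return(list(radius = R, saturated = TRUE, censored = FALSE))
  }
  radius <- if (interpolation == "nearest" || !is.finite(tstar[k + 1])) {
    # no finite bracket beyond the gated zone: the front stalls at the last
    # dying region (the Two-Step saturation radius)
    cr[k]
  } else {
    cr[k] + (tp - tstar[k]) / (tstar[k + 1] - tstar[k]) * (cr[k + 1] - cr[k])
  }
  list(radius = radius, saturated = FALSE, censored = FALSE)
}

#' Cell-death radius after a treatment duration
#'
#' Computes the per-region time-to-death profile and locates the radius at
#' which it crosses the treatment duration `tp`: cells inside die, cells
#' outside survive. The crossing is located by linear interpolation of the
#' time-to-death between the centre radii of the bracketing regions
#' (`interpolation = "nearest"` snaps to the last dying region instead).
#'
#' @inheritParams time_to_death
#' @param mesh The [build_mesh()] mesh.
#' @param tp Treatment duration (s).
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return A one-row tibble: `radius` (m), `saturated` (death reached the
#'   wall), `censored` (no death anywhere).
#' @export
death_radius <- function(field, mesh, params, tp,
                         samples_per_cycle = 1024L,
                         interpolation = c("linear", "nearest")) {
  stopifnot(inherits(params, "death_model"))
  if (tp <= 0) stop("death_radius: `tp` must be > 0", call. = FALSE)
  cyc <- .power_cycle(field, samples_per_cycle)
  gc <- .gated_cycle(cyc, params$pth_si)
  tstar <- .tstar_from_gated(gc, params$wth_si)
  res <- .radius_from_tstar(tstar, field$center_radius,
                            attr(mesh, "well_radius"), tp, interpolation)
  tibble::tibble(radius = res$radius, saturated = res$saturated,
                 censored = res$censored)
}

#' Death-radius-versus-duration curve
#'
#' Applies [death_radius()] across a set of treatment durations. Because the
#' gated accumulation is nondecreasing in time, the curve is monotone
#' nondecreasing in duration.
#'
#' @inheritParams death_radius
#' @param durations_ms Treatment durations in milliseconds (the reporting
#'   unit); default is the experimental grid
#'   `c(2, 3, 4, 6, 8, 10, 20, 30, 40, 50, 100)`.
#' @return A tibble of class `death_curve`: `duration_ms`, `radius_mm`,
#'   `saturated`, `censored`, with the `death_model` attached as attribute
#'   `params`.
#' @export
#' @examples
#' \donttest{
#' pip <- plasma_dose_field()
#' death_curve(pip$field, pip$mesh, death_model(pth = 7, wth = 0.3))
#' }
death_curve <- function(field, mesh, params,
                        durations_ms = c(2, 3, 4, 6, 8, 10, 20, 30, 40, 50, 100),
                        samples_per_cycle = 1024L,
                        interpolation = c("linear", "nearest")) {
  stopifnot(inherits(params, "death_model"))
  if (length(durations_ms) == 0 || any(durations_ms <= 0)) {
    stop("death_curve: `durations_ms` must be positive and nonempty",
         call. = FALSE)
  }
  interpolation <- match.arg(interpolation)
  cyc <- .power_cycle(field, samples_per_cycle)
  gc <- .gated_cycle(cyc, params$pth_si)
  tstar <- .tstar_from_gated(gc, params$wth_si)
  R <- attr(mesh, "well_radius")
  rows <- purrr::map(durations_ms, function(d) {
    .radius_from_tstar(tstar, field$center_radius, R, d / 1e3, interpolation)
  })
  out <- tibble::tibble(
    duration_ms = durations_ms,
    radius_mm = purrr::map_dbl(rows, "radius") * 1e3,
    saturated = purrr::map_lgl(rows, "saturated"),
    censored = purrr::map_lgl(rows, "censored")
  )
  structure(out, class = c("death_curve", class(out)), params = params)
}

#' Sensitivity sweep over threshold parameter grids
#'
#' Computes one death curve per `(pth, wth)` combination. Raising either
#' threshold can only shrink the predicted radius, so curves in a sweep are
#' pointwise ordered.
#'
#' @inheritParams death_curve
#' @param pth_values Power thresholds to sweep (uW/mm3).
#' @param wth_values Energy thresholds to sweep (uJ/mm3).
#' @param model Passed to [death_model()].
#' @return A tibble with columns `pth`, `wth`, `duration_ms`, `radius_mm`,
#'   `saturated`, `censored`; empty (0 rows) for an empty grid.
#' @export
sensitivity_sweep <- function(field, mesh, pth_values, wth_values,
                              durations_ms = c(2, 3, 4, 6, 8, 10, 20, 30, 40, 50, 100),
                              model = "two_step",
                              samples_per_cycle = 1024L) {
  grid <- expand.grid(pth = pth_values, wth = wth_values)
  if (nrow(grid) == 0) {
    return(tibble::tibble(pth = numeric(), wth = numeric(),
                          duration_ms = numeric(), radius_mm = numeric(),
                          saturated = logical(), censored = logical()))
  }
  purrr::pmap_dfr(grid, function(pth, wth) {
    cv <- death_curve(field, mesh,
                      death_model(pth = pth, wth = wth, model = model),
                      durations_ms, samples_per_cycle)
    dplyr::mutate(tibble::as_tibble(cv), pth = pth, wth = wth,
                  .before = 1)
  })
}

#' Write a death curve (or sweep) as CSV
#'
#' @param curve A `death_curve` or sweep tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_death_curve_csv <- function(curve, path) {
  out <- tibble::as_tibble(curve)
  if (!is.null(attr(curve, "params")) && !"pth" %in% names(out)) {
    p <- attr(curve, "params")
    out <- dplyr::mutate(out, Pth_uW_mm3 = p$pth, Wth_uJ_mm3 = p$wth)
  } else if ("pth" %in% names(out)) {
    out <- dplyr::rename(out, Pth_uW_mm3 = "pth", Wth_uJ_mm3 = "wth")
  }
  readr::write_csv(out, path)
  invisible(path)
}
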