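# Grid-search fitting of the Two-Step thresholds (Pth, Wth) to a
# radius-versus-duration dataset, and estimation of the duration-dependent
# effective power threshold in the short-duration regime.

#' Construct a radius-versus-duration experiment dataset
#'
#' @param data A data frame with columns `duration_ms`, `replicate`,
#'   `radius_mm` (one row per well measurement).
#' @return A tibble of class `plasma_experiment`.
#' @export
plasma_experiment <- function(data) {
  data <- tibble::as_tibble(data)
  needed <- c("duration_ms", "replicate", "radius_mm")
  if (!all(needed %in% names(data))) {
    stop("plasma_experiment: need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$radius_mm < 0) || any(data$duration_ms <= 0)) {
    stop("plasma_experiment: radii must be >= 0 and durations > 0",
         call. = FALSE)
  }
  structure(data[needed], class = c("plasma_experiment", class(data)))
}

#' Per-duration summary of an experiment dataset
#'
#' @param dataset A [plasma_experiment()].
#' @return A tibble with `duration_ms`, `mean_radius_mm`, `sd_radius_mm`,
#'   `n`, ordered by duration.
#' @export
dataset_summary <- function(dataset) {
  dataset |>
    dplyr::group_by(.data$duration_ms) |>
    dplyr::summarise(mean_radius_mm = mean(.data$radius_mm),
                     sd_radius_mm = stats::sd(.data$radius_mm),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$duration_ms)
}

# Model radii (mm) at the given durations for one (pth_si, wth_si), reusing
# a precomputed power cycle.
.model_radii_mm <- function(cycle, cr, R, durations_ms, pth_si, wth_si,
                            interpolation = "linear") {
  gc <- .gated_cycle(cycle, pth_si)
  tstar <- .tstar_from_gated(gc, wth_si)
  vapply(durations_ms, function(d) {
    .radius_from_tstar(tstar, cr, R, d / 1e3, interpolation)$radius
  }, numeric(1)) * 1e3
}

#' Fit the Two-Step thresholds to radius-versus-duration data
#'
#' Exhaustive grid search: for every `(pth, wth)` grid point the Two-Step
#' death curve is evaluated at the dataset's durations and scored by the
#' equal-weight sum of squared residuals against the per-duration mean radii
#' (mm^2). The coarse argmin is then refined once on a local grid at 5x
#' resolution. Ties are broken toward the smallest `pth`, then the smallest
#' `wth`, so the result is deterministic.
#'
#' If the best fit predicts no death at any duration (possible only for
#' degenerate data such as all-zero radii), the result lies on a ridge of
#' equivalent optima; the reported `wth` is then the grid maximum (the most
#' conservative representative) and the fit is flagged `degenerate`.
#'
#' @param dataset A [plasma_experiment()] with at least 2 distinct durations.
#' @param field A [cytoplasm_current_density()] dose field.
#' @param mesh The [build_mesh()] mesh.
#' @param pth_grid Power-threshold grid, uW/mm3 (default 0..20 by 0.5).
#' @param wth_grid Energy-threshold grid, uJ/mm3 (default 0.05..1 by 0.05).
#' @param refine Run the 5x local refinement (default TRUE).
#' @param samples_per_cycle Samples per drive cycle (default 1024).
#' @return An object of class `threshold_fit`: list with `best` (one-row
#'   tibble `pth`, `wth`, `objective_mm2`, `degenerate`), `grid` (coarse
#'   objective surface), `refined` (refined surface, NULL if `refine =
#'   FALSE`), `summary` (the per-duration data means), `durations_ms`.
#' @export
fit_thresholds <- function(dataset, field, mesh,
                           pth_grid = seq(0, 20, by = 0.5),
                           wth_grid = seq(0.05, 1, by = 0.05),
                           refine = TRUE,
                           samples_per_cycle = 1024L) {
  smry <- dataset_summary(dataset)
  if (nrow(smry) < 2) {
    stop("fit_thresholds: need >= 2 distinct durations; a single duration ",
         "leaves a ridge of equivalent optima", call. = FALSE)
  }
  durations_ms <- smry$duration_ms
  observed_mm <- smry$mean_radius_mm
  cycle <- .power_cycle(field, samples_per_cycle)
  cr <- field$center_radius
  R <- attr(mesh, "well_radius")

  eval_grid <- function(pths, wths) {
    purrr::map_dfr(sort(unique(pths)), function(p) {
      pth_si <- convert_power_density(p, "uW/mm3", "W/m3")
      gc <- .gated_cycle(cycle, pth_si)
      purrr::map_dfr(sort(unique(wths)), function(w) {
        wth_si <- convert_energy_density(w, "uJ/mm3", "J/m3")
        tstar <- .tstar_from_gated(gc, wth_si)
        # combos whose prediction violates the dead-disc premise (an inner
        # region outliving the front) are excluded from the search
        model_mm <- tryCatch(
          vapply(durations_ms, function(d) {
            .radius_from_tstar(tstar, cr, R, d / 1e3)$radius
          }, numeric(1)) * 1e3,
          error = function(e) NULL)
        if (is.null(model_mm)) {
          return(tibble::tibble(pth = p, wth = w, objective_mm2 = Inf,
                                all_censored = FALSE))
        }
        tibble::tibble(pth = p, wth = w,
                       objective_mm2 = sum((model_mm - observed_mm)^2),
                       all_censored = all(model_mm == 0))
      })
    })
  }
  pick_best <- function(grid) {
    grid |>
      dplyr::arrange(.data$objective_mm2, .data$pth, .data$wth) |>
      dplyr::slice(1)
  }

  coarse <- eval_grid(pth_grid, wth_grid)
  best <- pick_best(coarse)

  refined <- NULL
  if (refine) {
    pstep <- if (length(pth_grid) > 1) min(diff(sort(unique(pth_grid)))) else 0.5
    wstep <- if (length(wth_grid) > 1) min(diff(sort(unique(wth_grid)))) else 0.05
    pfine <- seq(max(0, best$pth - pstep), best$pth + pstep, by = pstep / 5)
    wfine <- seq(max(wstep / 5, best$wth - wstep), best$wth + wstep,
                 by = wstep / 5)
    refined <- eval_grid(pfine, wfine)
    best <- pick_best(refined)
  }

  degenerate <- isTRUE(best$all_censored)
  if (degenerate) {
    # walk the zero-death ridge to its most conservative representative
    ridge <- dplyr::filter(coarse, .data$all_censored)
    best <- ridge |>
      dplyr::arrange(.data$pth, dplyr::desc(.data$wth)) |>
      dplyr::slice(1)
  }
  structure(list(
    best = tibble::tibble(pth = best$pth, wth = best$wth,
                          objective_mm2 = best$objective_mm2,
                          degenerate = degenerate),
    grid = dplyr::select(coarse, -"all_censored"),
    refined = if (!is.null(refined)) dplyr::select(refined, -"all_censored"),
    summary = smry,
    durations_ms = durations_ms
  ), class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  b <- x$best
  cat(sprintf("<threshold_fit> Pth = %g uW/mm3, Wth = %g uJ/mm3 (SSR = %.4g mm2%s)\n",
              b$pth, b$wth, b$objective_mm2,
              if (b$degenerate) "; degenerate" else ""))
  invisible(x)
}

#' @rdname fit_thresholds
#' @param x A `threshold_fit`.
#' @param ... Unused.
#' @method tidy threshold_fit
#' @export
tidy.threshold_fit <- function(x, ...) {
  grid <- if (!is.null(x$refined)) dplyr::bind_rows(
    dplyr::mutate(x$grid, stage = "coarse"),
    dplyr::mutate(x$refined, stage = "refined")
  ) else dplyr::mutate(x$grid, stage = "coarse")
  tibble::as_tibble(grid)
}

#' @rdname fit_thresholds
#' @method glance threshold_fit
#' @export
glance.threshold_fit <- function(x, ...) {
  dplyr::mutate(x$best,
                n_durations = length(x$durations_ms),
                rmse_mm = sqrt(.data$objective_mm2 / length(x$durations_ms)))
}

#' Write a threshold fit as JSON
#'
#' @param fit A `threshold_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    best_Pth_uW_mm3 = fit$best$pth,
    best_Wth_uJ_mm3 = fit$best$wth,
    objective_mm2 = fit$best$objective_mm2,
    degenerate = fit$best$degenerate,
    durations_ms = fit$durations_ms,
    grid = fit$grid,
    refined = fit$refined
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Duration-dependent effective power threshold (short durations)
#'
#' For each short duration (<= `max_duration_ms`) the observed mean radius is
#' inverted into the `pth` that would make the Two-Step model reproduce it at
#' the fixed `wth`, by bisection over `bracket`. The death radius is
#' nonincreasing in `pth`, so the root is well defined whenever the observed
#' radius lies in the attainable range; outside it the entry is flagged
#' non-convergent and carries no value. A rising profile toward short
#' durations is the signature of cells tolerating brief, intense stimuli.
#'
#' @param dataset A [plasma_experiment()] restricted to (or containing) the
#'   short-duration regime.
#' @param field A dose field.
#' @param mesh The mesh.
#' @param wth Fixed energy threshold (uJ/mm3).
#' @param bracket Power-threshold search interval, uW/mm3 (default
#'   `c(0, 30)`).
#' @param max_duration_ms Upper end of the short-duration regime (default 10).
#' @param tol Convergence tolerance as a fraction of the bracket width
#'   (default 0.005).
#' @param samples_per_cycle Samples per drive cycle (default 1024).
#' @return A tibble of class `pth_profile`: `duration_ms`,
#'   `observed_radius_mm`, `effective_pth` (uW/mm3, NA when not converged),
#'   `converged`.
#' @export
effective_pth <- function(dataset, field, mesh, wth,
                          bracket = c(0, 30),
                          max_duration_ms = 10,
                          tol = 0.005,
                          samples_per_cycle = 1024L) {
  if (length(bracket) != 2 || bracket[1] < 0 || diff(bracket) <= 0) {
    stop("effective_pth: `bracket` must be an increasing non-negative interval",
         call. = FALSE)
  }
  smry <- dataset_summary(dataset) |>
    dplyr::filter(.data$duration_ms <= max_duration_ms)
  if (nrow(smry) == 0) {
    stop("effective_pth: no durations <= ", max_duration_ms, " ms in dataset",
         call. = FALSE)
  }
  cycle <- .power_cycle(field, samples_per_cycle)
  cr <- field$center_radius
  R <- attr(mesh, "well_radius")
  wth_si <- convert_energy_density(wth, "uJ/mm3", "J/m3")
  # Outer-front inversion: probing large gate values can switch off the
  # innermost annulus (whose lumped peak power sits below the interior
  # maximum) while regions beyond it still die; the observable death-circle
  # boundary is the outer front, so the sub-resolution core gap is tolerated
  # here rather than treated as a non-disc error.
  radius_at <- function(pth, d_ms) {
    pth_si <- convert_power_density(pth, "uW/mm3", "W/m3")
    gc <- .gated_cycle(cycle, pth_si)
    tstar <- .tstar_from_gated(gc, wth_si)
    .radius_from_tstar(tstar, cr, R, d_ms / 1e3,
                       allow_core_gap = TRUE)$radius * 1e3
  }
  tol_abs <- tol * diff(bracket)
  rows <- purrr::map2_dfr(smry$duration_ms, smry$mean_radius_mm,
                          function(d, r_obs) {
    lo <- bracket[1]; hi <- bracket[2]
    r_lo <- radius_at(lo, d); r_hi <- radius_at(hi, d)
    # radius is nonincreasing in pth: attainable range is [r_hi, r_lo]
    if (r_obs > r_lo || r_obs < r_hi) {
      return(tibble::tibble(duration_ms = d, observed_radius_mm = r_obs,
                            effective_pth = NA_real_, converged = FALSE))
    }
    while (hi - lo > tol_abs) {
      mid <- (lo + hi) / 2
      if (radius_at(mid, d) >= r_obs) lo <- mid else hi <- mid
    }
    tibble::tibble(duration_ms = d, observed_radius_mm = r_obs,
                   effective_pth = (lo + hi) / 2, converged = TRUE)
  })
  structure(rows, class = c("pth_profile", class(rows)),
            wth = wth, bracket = bracket)
}

#' Write an effective-Pth profile as CSV
#'
#' @param profile A [effective_pth()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pth_profile_csv <- function(profile, path) {
  out <- tibble::tibble(
    duration_ms = profile$duration_ms,
    effective_Pth_uW_mm3 = profile$effective_pth,
    converged = profile$converged
  )
  readr::write_csv(out, path)
  invisible(path)
}
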