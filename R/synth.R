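# Synthetic radius-versus-duration experiments with the statistical
# structure of the real assay: per duration, the mean radius is the forward
# Two-Step model prediction and replicates scatter around it with additive
# Gaussian noise (n wells per condition), truncated at zero. An optional
# short-duration suppression shrinks radii below 10 ms to emulate the
# observed tolerance of cells to brief stimuli, which is what the
# effective-Pth estimator is designed to detect.

# run `code` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic radius-versus-duration experiment
#'
#' @param field A [cytoplasm_current_density()] dose field.
#' @param mesh The [build_mesh()] mesh.
#' @param true_params The generating [death_model()].
#' @param durations_ms Treatment durations (ms); default the experimental
#'   grid `c(2, 3, 4, 6, 8, 10, 20, 30, 40, 50, 100)`.
#' @param noise_sd_mm Replicate noise SD in mm (default 0.02).
#' @param n_rep Wells per condition (default 4).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param short_suppression Optional fraction-per-decade deficit applied to
#'   durations <= 10 ms: the mean radius is multiplied by
#'   `max(0, 1 - short_suppression * log10(10 / duration_ms))`. `NULL`
#'   (default) disables it.
#' @param samples_per_cycle Samples per drive cycle for the forward model.
#' @return A [plasma_experiment()] tibble with attribute `generator` (a list
#'   echoing every generator parameter, for provenance sidecars).
#' @export
#' @examples
#' \donttest{
#' pip <- plasma_dose_field()
#' generate_dataset(pip$field, pip$mesh, death_model(pth = 7, wth = 0.3),
#'                  seed = 1)
#' }
generate_dataset <- function(field, mesh, true_params,
                             durations_ms = c(2, 3, 4, 6, 8, 10, 20, 30, 40, 50, 100),
                             noise_sd_mm = 0.02,
                             n_rep = 4L,
                             seed = 1L,
                             short_suppression = NULL,
                             samples_per_cycle = 1024L) {
  stopifnot(inherits(true_params, "death_model"))
  if (n_rep < 1) stop("generate_dataset: `n_rep` must be >= 1", call. = FALSE)
  if (noise_sd_mm < 0) stop("generate_dataset: `noise_sd_mm` must be >= 0",
                            call. = FALSE)
  if (any(durations_ms <= 0)) {
    stop("generate_dataset: durations must be positive", call. = FALSE)
  }
  curve <- death_curve(field, mesh, true_params, durations_ms,
                       samples_per_cycle)
  mean_mm <- curve$radius_mm
  if (!is.null(short_suppression)) {
    short <- durations_ms <= 10
    factor <- pmax(0, 1 - short_suppression * log10(10 / durations_ms[short]))
    mean_mm[short] <- mean_mm[short] * factor
  }
  dataset <- .with_seed(seed, {
    purrr::map2_dfr(durations_ms, mean_mm, function(d, mu) {
      tibble::tibble(
        duration_ms = d,
        replicate = seq_len(n_rep),
        radius_mm = pmax(0, mu + stats::rnorm(n_rep, 0, noise_sd_mm))
      )
    })
  })
  out <- plasma_experiment(dataset)
  attr(out, "generator") <- list(
    pth = true_params$pth, wth = true_params$wth, model = true_params$model,
    durations_ms = durations_ms, noise_sd_mm = noise_sd_mm, n_rep = n_rep,
    seed = seed, short_suppression = short_suppression,
    samples_per_cycle = samples_per_cycle
  )
  out
}

#' Write an experiment dataset as CSV (plus provenance sidecar)
#'
#' Writes the `duration_ms, replicate, radius_mm` CSV dialect the fitting
#' functions read; for a generated dataset, the generator parameters and
#' seed are echoed into `<path>.json`.
#'
#' @param dataset A [plasma_experiment()].
#' @param path Output CSV path.
#' @param sidecar Write the provenance JSON when generator metadata is
#'   present (default TRUE).
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path, sidecar = TRUE) {
  readr::write_csv(tibble::as_tibble(dataset)[, c("duration_ms", "replicate",
                                                  "radius_mm")], path)
  gen <- attr(dataset, "generator")
  if (sidecar && !is.null(gen)) {
    jsonlite::write_json(gen, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read an experiment dataset from CSV
#'
#' @param path CSV path with columns `duration_ms`, `replicate`, `radius_mm`.
#' @return A [plasma_experiment()].
#' @export
read_dataset_csv <- function(path) {
  plasma_experiment(readr::read_csv(path, show_col_types = FALSE))
}
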