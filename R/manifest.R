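#' Build a run manifest
#'
#' Captures everything needed to reproduce an analysis run: the fully
#' resolved configuration (defaults materialised, SI units), the seed, any
#' input/output paths, the package version and a timestamp. Write it next to
#' results with [write_manifest_json()].
#'
#' @param config A configuration list as from [default_config()] or
#'   [load_config()].
#' @param seed Optional integer seed used for any randomness in the run.
#' @param paths Optional named list of input/output paths.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config = default_config(), seed = NULL,
                         paths = list()) {
  structure(list(
    config = lapply(config, unclass),
    seed = seed,
    paths = paths,
    package = "plasmadose",
    version = as.character(utils::packageVersion("plasmadose")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Output JSON path.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
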