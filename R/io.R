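# Run configuration and result writing.

#' Read a run configuration (YAML or JSON)
#'
#' A configuration bundles the calibration, the height-map parameters, the
#' per-channel projection parameters and the deprojection options, so that
#' a run can be reproduced bit-for-bit from the file (stochastic steps are
#' seeded). Calibration must be explicit: there is no silent default for
#' `dz`, which scales every 3D metric.
#'
#' @param path `.yaml`/`.yml` or `.json` file with optional blocks
#'   `calibration` (dx, dy, dz), `heightmap` (fields of
#'   [height_map_params()]), `channels` (list of [channel_params()] fields),
#'   `deproj` (e.g. `median_cell_diameter`) and `seed`.
#' @return list with parsed `calibration`, `hm_params`, `proj_params`,
#'   `deproj`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON, got .", ext)
  hm <- if (!is.null(raw$heightmap)) do.call(height_map_params, raw$heightmap)
        else height_map_params()
  ch <- if (!is.null(raw$channels)) {
    if (is.data.frame(raw$channels))
      raw$channels <- split(raw$channels, seq_len(nrow(raw$channels)))
    lapply(raw$channels, function(p) do.call(channel_params, as.list(p)))
  } else list(channel_params())
  list(calibration = raw$calibration, hm_params = hm, proj_params = ch,
       deproj = raw$deproj, seed = raw$seed)
}

#' Write the outputs of a run with a checksum manifest
#'
#' Writes whatever is supplied: the projection (multi-channel float TIFF),
#' the height-map (float TIFF, 0-based slice values), per-cell metrics
#' (CSV), 3D contours (JSON) and the evaluation report (JSON), then a
#' `manifest.json` listing every file with its MD5 checksum.
#'
#' @param out_dir output directory (created if needed).
#' @param projection a `local_projection`, or `NULL`.
#' @param height_map matrix, or `NULL` (redundant when `projection` given).
#' @param cells a `deproj` result, or `NULL`.
#' @param report an `eval_report`, or `NULL`.
#' @return the manifest as a data.frame (file, md5), invisibly; also
#'   written to `manifest.json`.
#' @export
write_outputs <- function(out_dir, projection = NULL, height_map = NULL,
                          cells = NULL, report = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  if (!is.null(projection)) {
    pages <- unlist(projection$images, recursive = FALSE)
    write_tiff_float(pages, file.path(out_dir, "projection.tif"))
    files <- c(files, "projection.tif")
    if (is.null(height_map)) height_map <- projection$height_maps[[1]]
  }
  if (!is.null(height_map)) {
    write_height_map(height_map, file.path(out_dir, "heightmap.tif"))
    files <- c(files, "heightmap.tif")
  }
  if (!is.null(cells)) {
    utils::write.csv(cells$cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    contours <- lapply(cells$contours, function(m) {
      colnames(m) <- c("x", "y", "z"); as.data.frame(m)
    })
    jsonlite::write_json(contours, file.path(out_dir, "contours.json"),
                         digits = NA)
    files <- c(files, "cells.csv", "contours.json")
  }
  if (!is.null(report)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "report.json")
  }
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    row.names = NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
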