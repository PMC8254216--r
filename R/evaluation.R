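# Scoring projections and height-maps against ground truth.

#' Root-mean-square error between two grids
#'
#' @param a,b numeric matrices of equal size.
#' @param region optional logical matrix restricting the evaluation.
#' @return `sqrt(mean((a - b)^2))` over the region (default: all pixels).
#' @export
rmse <- function(a, b, region = NULL) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!all(dim(a) == dim(b))) stop("rmse: grids have different shapes")
  d <- a - b
  if (!is.null(region)) {
    stopifnot(all(dim(region) == dim(a)))
    d <- d[region]
  }
  sqrt(mean(d^2))
}

#' Score a projection and its height-map against ground truth
#'
#' @param proj projected 2D image (matrix) or a `local_projection` (channel
#'   1, timepoint 1 is scored).
#' @param ideal ground-truth surface-intensity image.
#' @param hm recovered height-map (1-based slices); optional.
#' @param hm_truth ground-truth height-map; required when `hm` is given.
#' @param region optional logical matrix restricting both RMSEs.
#' @param normalize `"none"` (default; fixtures share intensity scales) or
#'   `"zscore"` (both images standardised first, for cross-method
#'   comparisons).
#' @return an object of class `eval_report`: `projection_rmse` (intensity
#'   units), `heightmap_rmse` (slices, `NA` when no height-map given),
#'   `n_pixels`.
#' @export
evaluate_projection <- function(proj, ideal, hm = NULL, hm_truth = NULL,
                                region = NULL, normalize = c("none", "zscore")) {
  normalize <- match.arg(normalize)
  if (inherits(proj, "local_projection")) {
    if (is.null(hm)) hm <- proj$height_maps[[1]]
    proj <- projection_image(proj, 1L, 1L)
  }
  a <- proj; b <- ideal
  if (normalize == "zscore") {
    a <- (a - mean(a)) / stats::sd(a)
    b <- (b - mean(b)) / stats::sd(b)
  }
  hr <- NA_real_
  if (!is.null(hm)) {
    if (is.null(hm_truth)) stop("'hm_truth' is required to score a height-map")
    hr <- rmse(hm, hm_truth, region)
  }
  structure(list(projection_rmse = rmse(a, b, region),
                 heightmap_rmse = hr,
                 n_pixels = if (is.null(region)) length(ideal) else sum(region)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> projection RMSE = %.4g, height-map RMSE = %s slices (%d px)\n",
              x$projection_rmse,
              if (is.na(x$heightmap_rmse)) "NA" else sprintf("%.4g", x$heightmap_rmse),
              x$n_pixels))
  invisible(x)
}

#' Exhaustive parameter sweep minimising the projection RMSE
#'
#' Runs the full height-map + projection pipeline for every combination of
#' the supplied parameter values and returns the grid of RMSEs together
#' with the argmin parameter set. The sweep is exhaustive and deterministic
#' for a fixed grid.
#'
#' @param stack a `volume_stack`.
#' @param ideal ground-truth surface-intensity image.
#' @param hm_truth ground-truth height-map (scored alongside).
#' @param filter_kind,filter_window,binning,median_window vectors of
#'   candidate height-map parameters.
#' @param proj_params a [channel_params()] used for every candidate.
#' @return list with `results` (one data.frame row per combination, with
#'   `projection_rmse` and `heightmap_rmse`) and `best` (the argmin row).
#' @export
sweep_projection_params <- function(stack, ideal, hm_truth = NULL,
                                    filter_kind = "std",
                                    filter_window = c(5L, 11L, 21L),
                                    binning = 2L, median_window = 21L,
                                    proj_params = channel_params()) {
  grid <- expand.grid(filter_kind = filter_kind,
                      filter_window = filter_window,
                      binning = binning, median_window = median_window,
                      stringsAsFactors = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- height_map_params(filter_kind = grid$filter_kind[i],
                            filter_window = grid$filter_window[i],
                            binning = grid$binning[i],
                            median_window = grid$median_window[i])
    hm <- extract_height_map(stack, hp)
    img <- project_channel(stack, 1L, hm, proj_params)
    res[[i]] <- data.frame(
      grid[i, , drop = FALSE],
      projection_rmse = rmse(img, ideal),
      heightmap_rmse = if (is.null(hm_truth)) NA_real_ else rmse(hm, hm_truth),
      row.names = NULL)
  }
  results <- do.call(rbind, res)
  list(results = results,
       best = results[which.min(results$projection_rmse), , drop = FALSE])
}
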