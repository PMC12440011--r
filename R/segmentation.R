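#' Segmentation parameters
#'
#' Bundles the tunable parameters of the intact/detached quantification.
#' A single parameter set is meant to be used across a whole experiment,
#' mirroring standard practice of holding the threshold constant across
#' all images of a comparison.
#'
#' @param threshold_offset intensity units added to the estimated background
#'   to form the global threshold. `NULL` (default) derives the offset per
#'   image as `auto_k` times the median absolute deviation of the
#'   below-median pixel intensities (a robust spread of the non-signal
#'   pixels); a fixed numeric value gives exact reproducibility across runs.
#' @param auto_k multiplier for the robust-spread automatic offset.
#' @param connectivity pixel connectivity for component analysis, 4 or 8.
#' @param min_object_px components smaller than this are discarded as noise.
#' @param main_body_min_px minimum component area (px) to qualify as a main
#'   organoid body ("intact"); smaller surviving components are "detached".
#' @param ratio_epsilon_px floor for the detached-area denominator of the
#'   intact/detached ratio, so wells without detachment stay finite.
#' @return an object of class `segmentation_params`
#' @export
segmentation_params <- function(threshold_offset = NULL, auto_k = 3,
                                connectivity = 8, min_object_px = 4,
                                main_body_min_px = 200, ratio_epsilon_px = 1) {
  stopifnot(connectivity %in% c(4L, 8L),
            min_object_px >= 1, ratio_epsilon_px > 0)
  if (main_body_min_px <= min_object_px)
    stop("main_body_min_px must exceed min_object_px")
  if (!is.null(threshold_offset) && threshold_offset < 0)
    stop("threshold_offset must be >= 0")
  structure(list(threshold_offset = threshold_offset, auto_k = auto_k,
                 connectivity = as.integer(connectivity),
                 min_object_px = as.integer(min_object_px),
                 main_body_min_px = as.integer(main_body_min_px),
                 ratio_epsilon_px = ratio_epsilon_px),
            class = "segmentation_params")
}

#' Estimate the background intensity of a channel across an image set
#'
#' The background of a channel is the arithmetic mean, over all images in the
#' set, of each image's minimum pixel intensity in that channel. Using the
#' whole acquisition set (rather than a per-image value) keeps the threshold
#' comparable across conditions imaged together.
#'
#' @param images a list of multi-channel images (each a named list of
#'   numeric matrices, or a `multichannel_image`)
#' @param channel channel name
#' @return background intensity (scalar)
#' @export
estimate_background <- function(images, channel) {
  if (length(images) == 0) stop("image set is empty")
  minima <- vapply(seq_along(images), function(i) {
    img <- images[[i]]
    ch <- get_channel(img, channel)
    if (is.null(ch))
      stop(sprintf("channel '%s' missing from image %d", channel, i))
    min(ch)
  }, numeric(1))
  mean(minima)
}

#' Collapse a confocal z-stack to a single image
#'
#' @param stack a 3-d array (rows x cols x slices) or a list of equally
#'   sized matrices
#' @param method projection type: per-pixel `"max"` (default), `"mean"`
#'   or `"sum"`
#' @return a 2-d matrix
#' @export
z_project <- function(stack, method = c("max", "mean", "sum")) {
  method <- match.arg(method)
  if (is.list(stack)) {
    dims <- lapply(stack, dim)
    if (length(stack) == 0) stop("z-stack has no slices")
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
      stop("z-stack slices have ragged dimensions")
    stack <- array(unlist(stack), dim = c(dim(stack[[1]]), length(stack)))
  }
  if (length(dim(stack)) == 2) return(stack)
  stopifnot(length(dim(stack)) == 3)
  fun <- switch(method, max = max, mean = mean, sum = sum)
  apply(stack, c(1, 2), fun)
}

# Resolve the per-image threshold offset (fixed or robust automatic).
threshold_offset_for <- function(grid, params) {
  if (!is.null(params$threshold_offset)) return(params$threshold_offset)
  below <- grid[grid <= median(grid)]
  params$auto_k * mad(below, center = median(below))
}

#' Above-background foreground mask
#'
#' Pixels strictly brighter than `background + threshold_offset` are
#' foreground; connected components smaller than `min_object_px` are removed
#' as noise.
#'
#' @param grid 2-d intensity matrix
#' @param background background intensity (from [estimate_background()])
#' @param params a [segmentation_params()] object
#' @return logical matrix
#' @export
above_background_mask <- function(grid, background, params = segmentation_params()) {
  stopifnot(background >= 0)
  mask <- grid > background + threshold_offset_for(grid, params)
  if (!any(mask) || params$min_object_px <= 1) return(mask)
  labels <- segment_components(mask, params$connectivity)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= params$min_object_px)
  matrix(labels %in% keep, nrow(mask), ncol(mask))
}

#' Connected-component labeling
#'
#' Labels maximal connected foreground components 1..K under the stated
#' connectivity. Labeling order is deterministic: components are numbered by
#' the row-major position of their first pixel.
#'
#' @param mask logical matrix
#' @param connectivity 4 or 8
#' @return integer label matrix (0 = background)
#' @export
segment_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask))
  label_components_cpp(mask, as.integer(connectivity))
}

#' Partition labeled components into intact and detached classes
#'
#' Components with area at least `main_body_min_px` are classed as intact
#' (main organoid bodies); all other surviving components are detached
#' single cells or small clusters. If no component reaches the size cut, the
#' largest component is taken as the intact body, since an organoid must be
#' present in an analyzable image.
#'
#' @param labels integer label matrix from [segment_components()]
#' @param params a [segmentation_params()] object
#' @return list with integer vectors `intact` and `detached` (label ids) and
#'   the corresponding pixel areas
#' @export
classify_intact_detached <- function(labels, params = segmentation_params()) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0) stop("no above-background signal")
  areas <- tabulate(labels[labels > 0L], nbins = max(ids))[ids]
  intact <- ids[areas >= params$main_body_min_px]
  if (length(intact) == 0) intact <- ids[which.max(areas)]
  detached <- setdiff(ids, intact)
  list(intact = intact, detached = detached,
       intact_area_px = sum(areas[ids %in% intact]),
       detached_area_px = sum(areas[ids %in% detached]),
       areas = setNames(areas, ids))
}

#' Quantify one marker channel of one organoid image
#'
#' Runs the full channel quantification: optional z-projection, thresholding
#' against the set-level background, component analysis, intact/detached
#' partition, areas, ratio (with a floored denominator when no detached area
#' exists), and the background-subtracted mean intensity over the union mask,
#' optionally normalized to the control-condition mean.
#'
#' @param image a multi-channel image (named list of matrices / z-stacks)
#' @param channel channel name
#' @param background set-level background from [estimate_background()]
#' @param params a [segmentation_params()] object
#' @param control_stats optional list with `mean_intensity` of the control
#'   condition, used to normalize intensity
#' @return one-row data.frame (class also `segmentation_result`)
#' @export
quantify_channel <- function(image, channel, background,
                             params = segmentation_params(),
                             control_stats = NULL) {
  grid <- get_channel(image, channel)
  if (is.null(grid)) stop(sprintf("channel '%s' missing", channel))
  if (length(dim(grid)) == 3 || is.list(grid)) grid <- z_project(grid)
  mask <- above_background_mask(grid, background, params)
  labels <- segment_components(mask, params$connectivity)
  cls <- classify_intact_detached(labels, params)
  floored <- cls$detached_area_px < params$ratio_epsilon_px
  ratio <- cls$intact_area_px / max(cls$detached_area_px, params$ratio_epsilon_px)
  union_mask <- labels > 0L
  mean_int <- mean(pmax(grid[union_mask] - background, 0))
  norm_int <- NA_real_
  if (!is.null(control_stats)) {
    if (is.null(control_stats$mean_intensity) || control_stats$mean_intensity <= 0)
      stop("control mean intensity must be positive for normalization")
    norm_int <- mean_int / control_stats$mean_intensity
  }
  out <- data.frame(channel = channel,
                    intact_area_px = cls$intact_area_px,
                    detached_area_px = cls$detached_area_px,
                    intact_detached_ratio = ratio,
                    ratio_floored = floored,
                    mean_intensity = mean_int,
                    norm_intensity = norm_int,
                    stringsAsFactors = FALSE)
  attr(out, "labels") <- labels
  attr(out, "classes") <- cls
  class(out) <- c("segmentation_result", class(out))
  out
}

#' Live/dead area ratio
#'
#' Ratio of above-background area in the live (calcein, green) channel to
#' above-background area in the dead (propidium iodide, red) channel of a
#' whole-well image.
#'
#' @param green live-channel intensity matrix
#' @param red dead-channel intensity matrix
#' @param backgrounds named numeric vector with elements `green` and `red`
#' @param params a [segmentation_params()] object
#' @return list with `ratio`, the two areas, and `floored` flag (TRUE when
#'   the red area was below the denominator floor)
#' @export
live_dead_ratio <- function(green, red, backgrounds,
                            params = segmentation_params()) {
  stopifnot(all(dim(green) == dim(red)))
  ga <- sum(above_background_mask(green, backgrounds[["green"]], params))
  ra <- sum(above_background_mask(red, backgrounds[["red"]], params))
  floored <- ra < params$ratio_epsilon_px
  list(ratio = ga / max(ra, params$ratio_epsilon_px),
       green_area_px = ga, red_area_px = ra, floored = floored)
}

# Channel accessor tolerant of plain named lists and multichannel_image.
get_channel <- function(image, channel) {
  if (inherits(image, "multichannel_image")) return(image$channels[[channel]])
  image[[channel]]
}
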