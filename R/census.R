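#' Census parameters
#'
#' @param required_markers channels that must all show signal within one
#'   connected region for it to count as an organoid.
#' @param min_organoid_px minimum region area in pixels.
#' @param connectivity pixel connectivity, 4 or 8.
#' @return an object of class `census_params`
#' @export
census_params <- function(required_markers = c("ECAD", "PODXL", "LTL"),
                          min_organoid_px = 200, connectivity = 8) {
  stopifnot(length(required_markers) >= 2, min_organoid_px >= 1,
            connectivity %in% c(4L, 8L))
  structure(list(required_markers = required_markers,
                 min_organoid_px = as.integer(min_organoid_px),
                 connectivity = as.integer(connectivity)),
            class = "census_params")
}

#' Detect organoids in a whole-well image by marker coincidence
#'
#' A region counts as an organoid iff a connected component of the union of
#' the per-marker above-background masks has area at least `min_organoid_px`
#' and contains above-background pixels of every required marker.
#'
#' @param image a `multichannel_image`
#' @param backgrounds named numeric vector of per-channel backgrounds (from
#'   [estimate_background()])
#' @param params a [census_params()]
#' @param seg_params a [segmentation_params()] used for the per-channel masks
#' @return data.frame with one row per detected organoid: centroid
#'   (row/col), area, and per-marker presence flags
#' @export
detect_organoids <- function(image, backgrounds, params = census_params(),
                             seg_params = segmentation_params()) {
  marker_masks <- lapply(params$required_markers, function(ch) {
    grid <- get_channel(image, ch)
    if (is.null(grid))
      stop(sprintf("required marker channel '%s' missing", ch))
    if (length(dim(grid)) == 3) grid <- z_project(grid)
    above_background_mask(grid, backgrounds[[ch]], seg_params)
  })
  names(marker_masks) <- params$required_markers
  union_mask <- Reduce(`|`, marker_masks)
  labels <- segment_components(union_mask, params$connectivity)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0)
    return(data.frame(organoid = integer(0), row = numeric(0),
                      col = numeric(0), area_px = integer(0)))
  rows <- lapply(ids, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    if (nrow(px) < params$min_organoid_px) return(NULL)
    presence <- vapply(marker_masks, function(m) any(m[px]), logical(1))
    if (!all(presence)) return(NULL)
    cbind(data.frame(row = mean(px[, 1]), col = mean(px[, 2]),
                     area_px = nrow(px)), as.data.frame(t(presence)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(organoid = integer(0), row = numeric(0),
                      col = numeric(0), area_px = integer(0)))
  out <- do.call(rbind, rows)
  cbind(data.frame(organoid = seq_len(nrow(out))), out)
}

#' Percent of organoids remaining relative to day 0
#'
#' @param counts named numeric vector, day label -> organoid count; must
#'   include day `"0"` with a positive count
#' @return named numeric vector of percentages (day 0 = 100)
#' @export
percent_remaining <- function(counts) {
  if (!"0" %in% names(counts)) stop("counts must include day 0")
  if (counts[["0"]] <= 0) stop("day 0 count must be > 0")
  100 * counts / counts[["0"]]
}
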