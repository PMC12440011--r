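#' Match time-zero organoid positions to detections at a later time
#'
#' Greedy nearest-neighbour assignment: candidate pairs within
#' `max_displacement_px` are taken in ascending order of distance (ties
#' broken by the lower detection label), each t0 position and each detection
#' used at most once. Unmatched t0 positions are recorded as gaps.
#'
#' @param t0 data.frame with columns `id`, `row`, `col` (recorded positions
#'   at time zero); ids must be unique
#' @param detections data.frame with columns `label`, `row`, `col`
#' @param max_displacement_px maximum allowed displacement
#' @return data.frame with columns `id`, `label` (NA for a gap) and
#'   `distance`
#' @export
match_tracks <- function(t0, detections, max_displacement_px) {
  if (anyDuplicated(t0$id)) stop("duplicate t0 IDs")
  if (nrow(detections) == 0 || nrow(t0) == 0)
    return(data.frame(id = t0$id, label = NA_integer_,
                      distance = NA_real_))
  pairs <- expand.grid(i = seq_len(nrow(t0)), j = seq_len(nrow(detections)))
  pairs$distance <- sqrt((t0$row[pairs$i] - detections$row[pairs$j])^2 +
                         (t0$col[pairs$i] - detections$col[pairs$j])^2)
  pairs <- pairs[pairs$distance <= max_displacement_px, , drop = FALSE]
  pairs <- pairs[order(pairs$distance, detections$label[pairs$j]), , drop = FALSE]
  assigned <- data.frame(id = t0$id, label = NA_integer_, distance = NA_real_)
  used_t0 <- logical(nrow(t0)); used_det <- logical(nrow(detections))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (used_t0[i] || used_det[j]) next
    assigned$label[i] <- detections$label[j]
    assigned$distance[i] <- pairs$distance[k]
    used_t0[i] <- TRUE; used_det[j] <- TRUE
  }
  assigned
}

#' Per-organoid detachment trajectory from a tracked series
#'
#' Collates the per-timepoint quantification of one tracked organoid into a
#' trajectory of body area, detached area and detached object count, with
#' day-over-day deltas. Timepoints are sorted before computing deltas, so
#' input order does not matter.
#'
#' @param series data.frame with one row per matched timepoint and columns
#'   `time`, `body_area_px`, `detached_area_px`, `detached_count`
#' @param id optional organoid identifier carried into the output
#' @return data.frame of class `organoid_track`, sorted by time, with delta
#'   columns (`NA` at the first timepoint)
#' @export
track_metrics <- function(series, id = NA_character_) {
  req <- c("time", "body_area_px", "detached_area_px", "detached_count")
  if (!all(req %in% names(series)))
    stop("series must have columns time, body_area_px, detached_area_px, detached_count")
  if (nrow(series) < 2) stop("need at least 2 matched timepoints")
  if (anyDuplicated(series$time)) stop("duplicate timepoints")
  series <- series[order(series$time), , drop = FALSE]
  rownames(series) <- NULL
  out <- cbind(data.frame(id = id), series)
  out$d_body_area <- c(NA, diff(series$body_area_px))
  out$d_detached_area <- c(NA, diff(series$detached_area_px))
  out$d_detached_count <- c(NA, diff(series$detached_count))
  class(out) <- c("organoid_track", class(out))
  out
}
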