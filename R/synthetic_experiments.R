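#' Specification of per-condition effect sizes
#'
#' Defines a multi-condition experiment in terms of per-condition
#' multipliers applied to the baseline image specification. The defaults
#' mirror the magnitude of the high-glucose phenotype: a 3-fold reduction of
#' intact marker area and a matching increase in detached-cell burden in the
#' treated condition relative to control.
#'
#' @param conditions condition labels; must contain `control` exactly once.
#' @param control the control condition label (multiplier 1 enforced).
#' @param intact_multiplier named per-condition multiplier on intact body
#'   area (applied to the body radius as its square root).
#' @param detached_multiplier named per-condition multiplier on the
#'   detached-cell count.
#' @param n_organoids_per_condition organoids (one image each) per condition.
#' @param organoid_loss_fraction named vector day -> fraction of organoids
#'   lost by that day (drives the census ground truth); day 0 is implicit.
#' @param seed integer seed.
#' @return an object of class `effect_spec`
#' @export
effect_spec <- function(conditions = c("11mM", "33mM"), control = "11mM",
                        intact_multiplier = c("11mM" = 1, "33mM" = 1 / 3),
                        detached_multiplier = c("11mM" = 1, "33mM" = 2),
                        n_organoids_per_condition = 30,
                        organoid_loss_fraction = c("3" = 0.15, "6" = 0.30),
                        seed = 1) {
  if (sum(conditions == control) != 1)
    stop("conditions must include exactly one control")
  stopifnot(all(conditions %in% names(intact_multiplier)),
            all(conditions %in% names(detached_multiplier)),
            all(intact_multiplier > 0), all(detached_multiplier > 0))
  if (intact_multiplier[[control]] != 1 || detached_multiplier[[control]] != 1)
    stop("control condition multiplier must be 1")
  structure(list(conditions = conditions, control = control,
                 intact_multiplier = intact_multiplier,
                 detached_multiplier = detached_multiplier,
                 n_organoids_per_condition = as.integer(n_organoids_per_condition),
                 organoid_loss_fraction = organoid_loss_fraction,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

#' Generate a multi-condition synthetic experiment
#'
#' Produces one single-organoid image per organoid and condition, scaling
#' the body radius by the square root of the condition's intact-area
#' multiplier and the detached-cell count by the detached multiplier, plus a
#' manifest assigning each image a unique organoid identifier
#' (experiment/plate/well/organoid) and a census ground-truth table of
#' per-day organoid counts derived from the loss fractions.
#'
#' @param effects an [effect_spec()]
#' @param base an [image_spec()] describing the control condition
#' @return list with `records` (condition, organoid_id, image, truth),
#'   `manifest` (data.frame), and `counts_by_day` (condition, day,
#'   true_count)
#' @export
make_condition_experiment <- function(effects, base) {
  stopifnot(inherits(effects, "effect_spec"), inherits(base, "image_spec"))
  if (effects$n_organoids_per_condition < 2)
    stop("n_organoids_per_condition must be >= 2 (downstream statistics need replicates)")
  n <- effects$n_organoids_per_condition
  seeds <- withr::with_seed(effects$seed,
    matrix(sample.int(.Machine$integer.max - 1L, n * length(effects$conditions)),
           nrow = n))
  records <- list()
  manifest <- NULL
  for (j in seq_along(effects$conditions)) {
    cond <- effects$conditions[j]
    m_area <- effects$intact_multiplier[[cond]]
    m_det <- effects$detached_multiplier[[cond]]
    for (i in seq_len(n)) {
      sp <- base
      sp$body_radius_px <- base$body_radius_px * sqrt(m_area)
      cnt <- round(base$detached_cell_count * m_det)
      sp$detached_cell_count <- setNames(as.integer(cnt), names(cnt))
      sp$seed <- seeds[i, j]
      out <- make_organoid_image(sp)
      id <- sprintf("exp1/plate1/well%02d/org%03d", j, i)
      records[[length(records) + 1L]] <-
        list(condition = cond, organoid_id = id,
             image = out$image, truth = out$truth)
      manifest <- rbind(manifest, data.frame(
        organoid_id = id, condition = cond, day = 6L, seed = seeds[i, j],
        true_intact_area_px = sum(out$truth$intact$PODXL),
        true_detached_area_px = sum(out$truth$detached$PODXL),
        true_intact_fraction = out$truth$intact_fraction[["PODXL"]],
        stringsAsFactors = FALSE))
    }
  }
  days <- c(0, as.numeric(names(effects$organoid_loss_fraction)))
  loss <- c(0, unname(effects$organoid_loss_fraction))
  counts <- do.call(rbind, lapply(effects$conditions, function(cond) {
    data.frame(condition = cond, day = days,
               true_count = round(n * (1 - loss)), stringsAsFactors = FALSE)
  }))
  list(records = records, manifest = manifest, counts_by_day = counts,
       effects = effects, base = base)
}

#' Generate a synthetic time-lapse detachment series
#'
#' A single organoid whose body area shrinks by `shrink_rate` per day while
#' `shed_rate` new detached PODXL+ cells appear per day at fixed positions in
#' the ring band (detached cells accumulate; the detached mask is
#' non-decreasing over days). The body centroid drifts by at most
#' `max_drift_px` per day so position-based tracking from the day-0
#' coordinates is solvable.
#'
#' @param spec an [image_spec()] with `n_organoids = 1`
#' @param days number of frames (day 0 .. days-1); at least 2
#' @param shed_rate detached cells appearing per day
#' @param shrink_rate fraction of body area lost per day; must be < 1
#' @param max_drift_px maximum centroid drift per day
#' @return list of frames, each with `day`, `image`, `truth` (including
#'   `detached_count` and `body_area_px`)
#' @export
make_timelapse <- function(spec, days, shed_rate = 2, shrink_rate = 0.05,
                           max_drift_px = 2) {
  stopifnot(inherits(spec, "image_spec"), spec$n_organoids == 1)
  if (days < 2) stop("days must be >= 2")
  if (shrink_rate >= 1) stop("shrink_rate must be < 1")
  withr::with_seed(spec$seed, {
    nr <- spec$well_size_px[1]; nc <- spec$well_size_px[2]
    rad0 <- runif(1, spec$body_radius_px[1], spec$body_radius_px[2])
    ang0 <- runif(1, 0, 2 * pi)
    drift <- matrix(runif(2 * days, -max_drift_px, max_drift_px), ncol = 2)
    drift[1, ] <- 0
    center0 <- c(nr / 2, nc / 2)
    n_final <- round(shed_rate * (days - 1))
    # pre-draw all detached cell geometry once: angles evenly spaced (so
    # cells never collide), radial position and size drawn per cell
    cell_geom <- if (n_final > 0) {
      data.frame(
        a = runif(1, 0, 2 * pi) + 2 * pi * (seq_len(n_final) - 1) / n_final,
        dist_frac = runif(n_final),
        cr = runif(n_final, spec$detached_cell_radius_px[1],
                   spec$detached_cell_radius_px[2]))
    } else NULL
    reach <- 1.15 * rad0 + 1 + spec$detached_ring_px[2] +
      spec$detached_cell_radius_px[2] + max_drift_px * days + 2
    if (2 * reach > nr)
      stop(sprintf("ring band exceeds image bounds along height (%d px needed, %d available)",
                   ceiling(2 * reach), nr))
    if (2 * reach > nc)
      stop(sprintf("ring band exceeds image bounds along width (%d px needed, %d available)",
                   ceiling(2 * reach), nc))

    frames <- vector("list", days)
    for (t in seq_len(days) - 1L) {
      center <- center0 + colSums(drift[seq_len(t + 1), , drop = FALSE])
      rad <- rad0 * (1 - shrink_rate)^(t / 2)
      body <- matrix(FALSE, nr, nc)
      body <- add_disc(body, center[1], center[2], rad)
      for (a in ang0 + (0:2) * 2 * pi / 3)
        body <- add_disc(body, center[1] + 0.55 * rad * sin(a),
                         center[2] + 0.55 * rad * cos(a), 0.6 * rad)
      extent_t <- 1.15 * rad + 1   # current body reach; cells ride the ring
      n_cells <- round(shed_rate * t)
      det <- matrix(FALSE, nr, nc)
      if (n_cells > 0) {
        for (k in seq_len(n_cells)) {
          g <- cell_geom[k, ]
          span <- max(spec$detached_ring_px[2] - spec$detached_ring_px[1] - 2 * g$cr, 0)
          d <- extent_t + spec$detached_ring_px[1] + g$cr + g$dist_frac * span
          det <- add_disc(det, center[1] + d * sin(g$a),
                          center[2] + d * cos(g$a), g$cr)
        }
      }
      markers <- names(spec$channel_means)
      intact <- setNames(lapply(markers, function(ch) body), markers)
      detached <- setNames(lapply(markers, function(ch)
        if (ch == "PODXL") det else matrix(FALSE, nr, nc)), markers)
      channels <- setNames(lapply(markers, function(ch) {
        support <- intact[[ch]] | detached[[ch]]
        pmax(spec$background_mean + spec$channel_means[[ch]] * support +
               rnorm(nr * nc, sd = spec$noise_sd), 0)
      }), markers)
      tot <- sum(body) + sum(det)
      frames[[t + 1L]] <- list(
        day = t,
        image = structure(list(channels = channels, pixel_size = NULL),
                          class = "multichannel_image"),
        truth = structure(list(intact = intact, detached = detached,
                               intact_fraction = c(PODXL = sum(body) / tot),
                               detached_count = n_cells,
                               body_area_px = sum(body),
                               centroid = center,
                               organoid_count = 1L),
                          class = "ground_truth"))
    }
    frames
  })
}
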