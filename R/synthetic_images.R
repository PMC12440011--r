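#' Specification of a synthetic organoid well image
#'
#' Describes a whole-well, multi-channel fluorescence image containing one or
#' more organoid bodies (lobed unions of overlapping discs carrying the three
#' nephron markers PODXL, ECAD, LTL) surrounded by small detached single
#' cells/clusters in an annular band around each body. Units are pixels and
#' arbitrary intensity units throughout.
#'
#' @param well_size_px integer pair (rows, cols) of the image grid.
#' @param n_organoids number of organoid bodies in the well.
#' @param body_radius_px range (min, max) of the main body disc radius;
#'   each organoid draws its radius uniformly from this range.
#' @param detached_cell_count detached objects per organoid and channel:
#'   either a single count applied to every channel or a named vector with
#'   one count per channel.
#' @param detached_cell_radius_px range of detached-cell disc radii.
#' @param detached_ring_px distance band (min, max) from the body edge in
#'   which detached cells are placed; the lower bound must be positive so
#'   detached objects never touch the body.
#' @param channel_means named vector of foreground intensities; names must
#'   include PODXL, ECAD and LTL.
#' @param background_mean uniform background offset (intensity units).
#' @param noise_sd standard deviation of additive Gaussian noise (clipped
#'   at zero).
#' @param marker_overlap_fraction fraction of the body area carrying each
#'   marker; markers occupy overlapping sub-regions anchored at the body
#'   center (PODXL) and periphery (ECAD, LTL).
#' @param z_slices confocal slices per channel; slices share the signal and
#'   carry independent noise.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return an object of class `image_spec`
#' @export
image_spec <- function(well_size_px = c(192, 192), n_organoids = 1,
                       body_radius_px = c(20, 28), detached_cell_count = 8,
                       detached_cell_radius_px = c(2, 3),
                       detached_ring_px = c(4, 30),
                       channel_means = c(PODXL = 200, ECAD = 180, LTL = 160),
                       background_mean = 20, noise_sd = 8,
                       marker_overlap_fraction = 0.6, z_slices = 1, seed = 1) {
  stopifnot(length(well_size_px) == 2, all(well_size_px >= 16),
            n_organoids >= 1, length(body_radius_px) == 2,
            body_radius_px[1] > 0, diff(body_radius_px) >= 0,
            all(detached_cell_count >= 0),
            length(detached_cell_radius_px) == 2,
            detached_cell_radius_px[1] >= 1,
            length(detached_ring_px) == 2,
            marker_overlap_fraction > 0, marker_overlap_fraction <= 1,
            z_slices >= 1)
  if (detached_ring_px[1] <= 0)
    stop("detached_ring_px lower bound must be > 0 (detached objects never touch the body)")
  if (detached_ring_px[2] < detached_ring_px[1])
    stop("detached_ring_px must be an increasing range")
  if (any(channel_means < 0) || background_mean < 0 || noise_sd < 0)
    stop("intensities must be >= 0")
  if (!all(c("PODXL", "ECAD", "LTL") %in% names(channel_means)))
    stop("channel_means must include PODXL, ECAD and LTL")
  if (length(detached_cell_count) > 1 &&
      !all(names(channel_means) %in% names(detached_cell_count)))
    stop("per-channel detached_cell_count must name every channel")
  structure(list(well_size_px = as.integer(well_size_px),
                 n_organoids = as.integer(n_organoids),
                 body_radius_px = body_radius_px,
                 detached_cell_count = setNames(as.integer(detached_cell_count),
                                                names(detached_cell_count)),
                 detached_cell_radius_px = detached_cell_radius_px,
                 detached_ring_px = detached_ring_px,
                 channel_means = channel_means,
                 background_mean = background_mean, noise_sd = noise_sd,
                 marker_overlap_fraction = marker_overlap_fraction,
                 z_slices = as.integer(z_slices), seed = as.integer(seed)),
            class = "image_spec")
}

# paint a filled disc into a logical mask (bounding-box vectorized)
add_disc <- function(mask, r0, c0, rad) {
  nr <- nrow(mask); nc <- ncol(mask)
  rs <- max(1L, floor(r0 - rad)):min(nr, ceiling(r0 + rad))
  cs <- max(1L, floor(c0 - rad)):min(nc, ceiling(c0 + rad))
  sub <- outer((rs - r0)^2, (cs - c0)^2, "+") <= rad^2
  mask[rs, cs] <- mask[rs, cs] | sub
  mask
}

# lobed organoid body: main disc plus three satellite discs
body_mask_at <- function(nr, nc, r0, c0, rad) {
  m <- matrix(FALSE, nr, nc)
  m <- add_disc(m, r0, c0, rad)
  ang <- runif(1, 0, 2 * pi) + (0:2) * 2 * pi / 3
  for (a in ang) m <- add_disc(m, r0 + 0.55 * rad * sin(a),
                               c0 + 0.55 * rad * cos(a), 0.6 * rad)
  m
}

# the farthest body pixel from the nominal center (ring band reference)
body_extent <- function(body, r0, c0) {
  px <- which(body, arr.ind = TRUE)
  sqrt(max((px[, 1] - r0)^2 + (px[, 2] - c0)^2))
}

# marker sub-region: the fraction of body pixels nearest to an anchor point
marker_region <- function(body, anchor_r, anchor_c, fraction) {
  px <- which(body, arr.ind = TRUE)
  d <- (px[, 1] - anchor_r)^2 + (px[, 2] - anchor_c)^2
  cut <- quantile(d, fraction, type = 1)
  keep <- px[d <= cut, , drop = FALSE]
  m <- matrix(FALSE, nrow(body), ncol(body))
  m[keep] <- TRUE
  m
}

#' Generate a synthetic organoid well image with ground truth
#'
#' Bodies are unions of overlapping discs; each nephron marker occupies a
#' configurable sub-region of the body (PODXL central, ECAD/LTL peripheral,
#' all overlapping near the body center). Detached cells are isolated discs
#' in the ring band around each body, placed per channel and guaranteed not
#' to touch the body or each other. Ground-truth masks are exactly the
#' noiseless object supports.
#'
#' @param spec an [image_spec()]
#' @return list with `image` (a `multichannel_image`) and `truth` (a
#'   `ground_truth` with per-channel intact/detached masks, intact
#'   fractions, organoid count and body centroids)
#' @export
make_organoid_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  withr::with_seed(spec$seed, generate_well(spec))
}

generate_well <- function(spec) {
  nr <- spec$well_size_px[1]; nc <- spec$well_size_px[2]
  r_max <- spec$body_radius_px[2]
  cr_max <- spec$detached_cell_radius_px[2]
  # reach of the lobed body (satellite at 0.55r with radius 0.6r) plus ring
  needed <- 1.15 * r_max + 1 + spec$detached_ring_px[2] + cr_max + 2
  centers <- place_body_centers(spec$n_organoids, nr, nc, needed)

  markers <- names(spec$channel_means)
  intact <- lapply(markers, function(ch) matrix(FALSE, nr, nc))
  detached <- lapply(markers, function(ch) matrix(FALSE, nr, nc))
  names(intact) <- names(detached) <- markers
  blocked <- matrix(FALSE, nr, nc)   # bodies + already-placed cells, for isolation
  centroids <- data.frame(organoid = integer(0), row = numeric(0), col = numeric(0))

  bodies <- vector("list", spec$n_organoids)
  for (i in seq_len(spec$n_organoids)) {
    rad <- runif(1, spec$body_radius_px[1], spec$body_radius_px[2])
    body <- body_mask_at(nr, nc, centers[i, 1], centers[i, 2], rad)
    bodies[[i]] <- list(mask = body, r0 = centers[i, 1], c0 = centers[i, 2],
                        rad = rad,
                        extent = body_extent(body, centers[i, 1], centers[i, 2]))
    blocked <- blocked | body
    px <- which(body, arr.ind = TRUE)
    centroids <- rbind(centroids, data.frame(organoid = i,
                                             row = mean(px[, 1]),
                                             col = mean(px[, 2])))
    for (ch in markers) {
      anchor <- switch(ch,
                       PODXL = c(0, 0),
                       ECAD = c(0, 0.5 * rad),
                       LTL = c(0, -0.5 * rad),
                       c(0.5 * rad, 0))
      intact[[ch]] <- intact[[ch]] |
        marker_region(body, centers[i, 1] + anchor[1], centers[i, 2] + anchor[2],
                      spec$marker_overlap_fraction)
    }
  }

  for (i in seq_len(spec$n_organoids)) {
    b <- bodies[[i]]
    for (ch in markers) {
      cnt <- spec$detached_cell_count
      n_cells <- if (length(cnt) > 1) cnt[[ch]] else cnt
      if (n_cells == 0) next
      placed <- place_detached_cells(n_cells, b, spec, nr, nc, blocked)
      detached[[ch]] <- detached[[ch]] | placed$mask
      blocked <- placed$blocked
    }
  }

  channels <- lapply(markers, function(ch) {
    support <- intact[[ch]] | detached[[ch]]
    signal <- spec$background_mean + spec$channel_means[[ch]] * support
    if (spec$z_slices == 1) {
      pmax(signal + rnorm(nr * nc, sd = spec$noise_sd), 0)
    } else {
      arr <- array(0, dim = c(nr, nc, spec$z_slices))
      for (z in seq_len(spec$z_slices))
        arr[, , z] <- pmax(signal + rnorm(nr * nc, sd = spec$noise_sd), 0)
      arr
    }
  })
  names(channels) <- markers

  f <- vapply(markers, function(ch) {
    tot <- sum(intact[[ch]]) + sum(detached[[ch]])
    if (tot == 0) NA_real_ else sum(intact[[ch]]) / tot
  }, numeric(1))

  list(image = structure(list(channels = channels, pixel_size = NULL),
                         class = "multichannel_image"),
       truth = structure(list(intact = intact, detached = detached,
                              intact_fraction = f,
                              organoid_count = spec$n_organoids,
                              centroids = centroids,
                              body_area_px = sum(Reduce(`|`, lapply(bodies, `[[`, "mask")))),
                         class = "ground_truth"))
}

place_body_centers <- function(n, nr, nc, needed) {
  if (n == 1) {
    if (2 * needed > nr)
      stop(sprintf("ring band exceeds image bounds along height (%d px needed, %d available)",
                   ceiling(2 * needed), nr))
    if (2 * needed > nc)
      stop(sprintf("ring band exceeds image bounds along width (%d px needed, %d available)",
                   ceiling(2 * needed), nc))
    return(matrix(c(nr / 2, nc / 2), 1, 2))
  }
  nx <- ceiling(sqrt(n)); ny <- ceiling(n / nx)
  cell_h <- nr / ny; cell_w <- nc / nx
  if (cell_h < 2 * needed)
    stop(sprintf("ring band exceeds image bounds along height (cell %.0f px, %.0f needed)",
                 cell_h, 2 * needed))
  if (cell_w < 2 * needed)
    stop(sprintf("ring band exceeds image bounds along width (cell %.0f px, %.0f needed)",
                 cell_w, 2 * needed))
  cells <- sample(nx * ny, n)
  jit_h <- cell_h / 2 - needed; jit_w <- cell_w / 2 - needed
  t(vapply(cells, function(k) {
    ix <- (k - 1) %% nx; iy <- (k - 1) %/% nx
    c((iy + 0.5) * cell_h + runif(1, -jit_h, jit_h),
      (ix + 0.5) * cell_w + runif(1, -jit_w, jit_w))
  }, numeric(2)))
}

place_detached_cells <- function(n_cells, body, spec, nr, nc, blocked) {
  mask <- matrix(FALSE, nr, nc)
  ring <- spec$detached_ring_px
  placed <- 0L; tries <- 0L
  cells <- list()
  while (placed < n_cells) {
    tries <- tries + 1L
    if (tries > 400L * n_cells)
      stop("could not place detached cells: ring band too crowded")
    cr <- runif(1, spec$detached_cell_radius_px[1], spec$detached_cell_radius_px[2])
    d <- runif(1, body$extent + ring[1] + cr, body$extent + ring[2])
    a <- runif(1, 0, 2 * pi)
    r0 <- body$r0 + d * sin(a); c0 <- body$c0 + d * cos(a)
    if (r0 - cr < 3 || r0 + cr > nr - 2 || c0 - cr < 3 || c0 + cr > nc - 2) next
    ok <- TRUE
    for (cl in cells) {
      if ((r0 - cl[1])^2 + (c0 - cl[2])^2 < (cr + cl[3] + 2)^2) { ok <- FALSE; break }
    }
    if (!ok) next
    # isolation check restricted to the padded bounding box of the disc;
    # keep a >1 px gap to everything already painted (no diagonal contact)
    rs <- floor(r0 - cr - 1):ceiling(r0 + cr + 1)
    cs <- floor(c0 - cr - 1):ceiling(c0 + cr + 1)
    sub <- outer((rs - r0)^2, (cs - c0)^2, "+") <= cr^2
    if (any(dilate1(sub) & blocked[rs, cs])) next
    mask[rs, cs] <- mask[rs, cs] | sub
    blocked[rs, cs] <- blocked[rs, cs] | sub
    cells[[length(cells) + 1L]] <- c(r0, c0, cr)
    placed <- placed + 1L
  }
  list(mask = mask, blocked = blocked)
}

# one-pixel 8-neighbourhood dilation, used to enforce object isolation
dilate1 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  v <- m
  v[-1, ] <- v[-1, ] | m[-nr, ]
  v[-nr, ] <- v[-nr, ] | m[-1, ]
  out <- v
  out[, -1] <- out[, -1] | v[, -nc]
  out[, -nc] <- out[, -nc] | v[, -1]
  out
}
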