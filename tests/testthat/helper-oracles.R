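# Independent oracles used across tests. These deliberately re-derive
# results by brute force and stay out of the package's code paths.

# Flood-fill connected-component labeling (BFS), labels numbered by the
# row-major position of each component's first pixel.
flood_fill_labels <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    nb <- cbind(rep(c(-1, 0, 1), each = 3), rep(c(-1, 0, 1), 3))
    nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  }
  nxt <- 0L
  qr <- integer(nr * nc); qc <- integer(nr * nc)   # preallocated BFS queue
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || labels[r, c] != 0L) next
    nxt <- nxt + 1L
    head <- 1L; tail <- 1L
    qr[1] <- r; qc[1] <- c
    labels[r, c] <- nxt
    while (head <= tail) {
      r0 <- qr[head]; c0 <- qc[head]; head <- head + 1L
      for (k in seq_len(nrow(nb))) {
        rr <- r0 + nb[k, 1]; cc <- c0 + nb[k, 2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && labels[rr, cc] == 0L) {
          labels[rr, cc] <- nxt
          tail <- tail + 1L
          qr[tail] <- rr; qc[tail] <- cc
        }
      }
    }
  }
  labels
}

random_mask <- function(nr = 32, nc = 32, p = 0.35) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# Hand-coded one-way ANOVA sums of squares (textbook decomposition).
anova_F_oracle <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  list(F = (ssb / dfb) / (ssw / dfw), df_between = dfb, df_within = dfw,
       mse = ssw / dfw)
}

# Brute-force re-application of the four QC rules to a counts matrix.
qc_oracle <- function(counts, thr) {
  genes <- rownames(counts)
  keep <- character(0)
  for (ci in seq_len(ncol(counts))) {
    col <- as.numeric(counts[, ci])
    total <- sum(col)
    detected <- sum(col > 0)
    mito <- sum(col[grepl("^MT-", genes)])
    ribo <- sum(col[grepl("^RPS|^RPL", genes)])
    mito_f <- if (total > 0) mito / total else 0
    ribo_f <- if (total > 0) ribo / total else 0
    if (total < thr$max_umi && detected < thr$max_genes &&
        mito_f < thr$max_mito_fraction && ribo_f < thr$max_ribo_fraction)
      keep <- c(keep, colnames(counts)[ci])
  }
  keep
}

# Small, fast image spec used widely in tests: single organoid, clean SNR.
test_image_spec <- function(seed = 1, ...) {
  args <- list(well_size_px = c(128, 128), body_radius_px = c(14, 18),
               detached_cell_count = 5, detached_cell_radius_px = c(2, 3),
               detached_ring_px = c(3, 18), background_mean = 20,
               noise_sd = 6, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(image_spec, args)
}

test_seg_params <- function(...) {
  args <- list(threshold_offset = 60, main_body_min_px = 100,
               min_object_px = 4)
  args[names(list(...))] <- list(...)
  do.call(segmentation_params, args)
}
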