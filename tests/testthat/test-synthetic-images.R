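test_that("generation is deterministic and leaves the global RNG alone", {
  sp <- test_image_spec(seed = 5)
  set.seed(999); before <- .Random.seed
  a <- make_organoid_image(sp)
  expect_identical(.Random.seed, before)
  b <- make_organoid_image(sp)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$intact, b$truth$intact)
})

test_that("truth masks are disjoint and equal the noiseless support", {
  sp <- test_image_spec(seed = 2, noise_sd = 0)
  out <- make_organoid_image(sp)
  for (ch in c("PODXL", "ECAD", "LTL")) {
    intact <- out$truth$intact[[ch]]; det <- out$truth$detached[[ch]]
    expect_false(any(intact & det))
    support <- out$image$channels[[ch]] > sp$background_mean
    expect_identical(intact | det, support)
  }
})

test_that("no detached objects means intact fraction one", {
  out <- make_organoid_image(test_image_spec(seed = 3, detached_cell_count = 0))
  expect_false(any(out$truth$detached$PODXL))
  expect_equal(out$truth$intact_fraction[["PODXL"]], 1.0)
})

test_that("intact fraction equals the pixel-count of the emitted masks", {
  sp <- test_image_spec(seed = 7, noise_sd = 0, detached_cell_count = 10,
                        body_radius_px = c(16, 16),
                        detached_cell_radius_px = c(3, 3),
                        marker_overlap_fraction = 1)
  out <- make_organoid_image(sp)
  for (ch in c("PODXL", "ECAD", "LTL")) {
    f_oracle <- sum(out$truth$intact[[ch]]) /
      (sum(out$truth$intact[[ch]]) + sum(out$truth$detached[[ch]]))
    expect_equal(out$truth$intact_fraction[[ch]], f_oracle)
  }
  # 10 detached cells per channel, each its own component
  labs <- flood_fill_labels(out$truth$detached$PODXL, 8)
  expect_equal(max(labs), 10)
})

test_that("a ring band that cannot fit is rejected naming the dimension", {
  expect_error(make_organoid_image(
    test_image_spec(well_size_px = c(40, 128), detached_ring_px = c(3, 30))),
    "height")
  expect_error(make_organoid_image(
    test_image_spec(well_size_px = c(128, 40), detached_ring_px = c(3, 30))),
    "width")
  expect_error(image_spec(detached_ring_px = c(0, 10)), "lower bound")
})

test_that("condition multipliers are realized in the emitted ground truth", {
  eff <- effect_spec(intact_multiplier = c("11mM" = 1, "33mM" = 1 / 3),
                     detached_multiplier = c("11mM" = 1, "33mM" = 2),
                     n_organoids_per_condition = 30, seed = 17)
  exp1 <- make_condition_experiment(eff, test_image_spec())
  man <- exp1$manifest
  m_ctrl <- mean(man$true_intact_area_px[man$condition == "11mM"])
  m_trt <- mean(man$true_intact_area_px[man$condition == "33mM"])
  expect_lt(abs(m_ctrl / m_trt - 3), 0.35)
  expect_equal(nrow(man), 60)
  expect_false(anyDuplicated(man$organoid_id) > 0)
})

test_that("single-condition experiments are valid with unit fold change", {
  eff <- effect_spec(conditions = "11mM", control = "11mM",
                     intact_multiplier = c("11mM" = 1),
                     detached_multiplier = c("11mM" = 1),
                     n_organoids_per_condition = 3, seed = 1)
  exp1 <- make_condition_experiment(eff, test_image_spec())
  g <- split(exp1$manifest$true_intact_area_px, exp1$manifest$condition)
  expect_equal(unname(fold_change(g, "11mM")), 1)
})

test_that("census ground truth follows the loss fractions", {
  eff <- effect_spec(n_organoids_per_condition = 20,
                     organoid_loss_fraction = c("3" = 0.15, "6" = 0.30), seed = 2)
  exp1 <- make_condition_experiment(eff, test_image_spec())
  cts <- exp1$counts_by_day[exp1$counts_by_day$condition == "33mM", ]
  expect_equal(cts$true_count[cts$day == 0], 20)
  expect_equal(cts$true_count[cts$day == 3], round(20 * 0.85))
  expect_equal(cts$true_count[cts$day == 6], round(20 * 0.70))
  expect_error(make_condition_experiment(
    effect_spec(n_organoids_per_condition = 1), test_image_spec()),
    "replicates")
})

test_that("invalid effect specs are rejected", {
  expect_error(effect_spec(conditions = c("a", "b"), control = "c"), "control")
  expect_error(effect_spec(intact_multiplier = c("11mM" = 2, "33mM" = 1)),
               "multiplier must be 1")
})

test_that("time-lapse truth follows the shed and shrink schedule", {
  tl <- make_timelapse(test_image_spec(seed = 3, noise_sd = 0,
                                       well_size_px = c(160, 160)),
                       days = 6, shed_rate = 2, shrink_rate = 0.05)
  expect_equal(vapply(tl, function(f) f$truth$detached_count, numeric(1)),
               c(0, 2, 4, 6, 8, 10))
  areas <- vapply(tl, function(f) f$truth$body_area_px, numeric(1))
  expect_true(all(diff(areas) <= 0))
  f <- vapply(tl, function(fr) fr$truth$intact_fraction[["PODXL"]], numeric(1))
  expect_true(all(diff(f) <= 0))
})

test_that("a static time-lapse has constant ground truth", {
  tl <- make_timelapse(test_image_spec(seed = 4, noise_sd = 0,
                                       well_size_px = c(160, 160)),
                       days = 3, shed_rate = 0, shrink_rate = 0,
                       max_drift_px = 0)
  expect_identical(tl[[1]]$truth$intact, tl[[3]]$truth$intact)
  expect_equal(tl[[1]]$truth$body_area_px, tl[[2]]$truth$body_area_px)
})

test_that("time-lapse input contracts are enforced", {
  sp <- test_image_spec(well_size_px = c(160, 160))
  expect_error(make_timelapse(sp, days = 1), "days")
  expect_error(make_timelapse(sp, days = 4, shrink_rate = 1), "shrink_rate")
})
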