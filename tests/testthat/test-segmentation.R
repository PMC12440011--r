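test_that("background is the mean of per-image channel minima", {
  imgs <- list(list(PODXL = matrix(10:13, 2, 2)),
               list(PODXL = matrix(20:23, 2, 2)),
               list(PODXL = matrix(30:33, 2, 2)))
  expect_equal(estimate_background(imgs, "PODXL"), 20)
  expect_equal(estimate_background(list(list(PODXL = matrix(0, 3, 3))), "PODXL"), 0)

  set.seed(3)
  imgs <- replicate(50, list(PODXL = matrix(runif(64, 0, 100), 8, 8)),
                    simplify = FALSE)
  oracle <- mean(vapply(imgs, function(im) min(im$PODXL), numeric(1)))
  expect_equal(estimate_background(imgs, "PODXL"), oracle)
})

test_that("missing channels and empty sets are rejected with context", {
  expect_error(estimate_background(list(), "PODXL"), "empty")
  imgs <- list(list(PODXL = matrix(1, 2, 2)), list(ECAD = matrix(1, 2, 2)))
  expect_error(estimate_background(imgs, "PODXL"), "image 2")
})

test_that("z-projection matches the per-pixel elementwise oracle", {
  expect_equal(z_project(list(matrix(1), matrix(5))), matrix(5))
  m <- matrix(rnorm(16), 4, 4)
  expect_equal(z_project(list(m)), m)

  set.seed(11)
  stack <- array(rnorm(16 * 16 * 5), dim = c(16, 16, 5))
  oracle <- matrix(0, 16, 16)
  for (r in 1:16) for (c in 1:16) oracle[r, c] <- max(stack[r, c, ])
  expect_equal(z_project(stack), oracle)
  expect_equal(z_project(stack, "mean"),
               apply(stack, c(1, 2), mean))
  expect_error(z_project(list(matrix(0, 2, 2), matrix(0, 3, 3))), "ragged")
})

test_that("above-background mask thresholds and removes small objects", {
  p <- segmentation_params(threshold_offset = 5, min_object_px = 4,
                           main_body_min_px = 50)
  grid <- matrix(10, 20, 20)
  expect_false(any(above_background_mask(grid, 10, p)))

  grid[5:7, 5:7] <- 10 + 2 * 5   # one 9-px square, clearly above threshold
  expect_equal(sum(above_background_mask(grid, 10, p)), 9)

  set.seed(5)
  grid <- matrix(runif(32 * 32, 0, 30), 32, 32)
  mask <- above_background_mask(grid, 10, p)
  raw <- grid > 15
  labs <- flood_fill_labels(raw, 8)
  sizes <- tabulate(labs[labs > 0])
  oracle <- raw & matrix(labs %in% which(sizes >= 4), 32, 32)
  expect_identical(mask, oracle)
})

test_that("component labeling respects connectivity and matches flood fill", {
  m <- matrix(FALSE, 2, 2); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(max(segment_components(m, 4)), 2)
  expect_equal(max(segment_components(m, 8)), 1)
  expect_equal(max(segment_components(matrix(TRUE, 3, 3), 4)), 1)

  set.seed(42)
  for (i in 1:25) {
    mask <- random_mask()
    for (conn in c(4, 8))
      expect_identical(segment_components(mask, conn),
                       flood_fill_labels(mask, conn))
  }
})

test_that("intact/detached classification applies the area rule", {
  p <- segmentation_params(main_body_min_px = 50, min_object_px = 4)
  lab <- matrix(0L, 40, 40)
  lab[5:24, 5:24] <- 1L                      # 400 px body
  cls <- classify_intact_detached(lab, p)
  expect_equal(cls$intact, 1L)
  expect_length(cls$detached, 0)

  lab[30, 30:34] <- 2L; lab[35, 30:34] <- 3L # two 5-px clusters
  cls <- classify_intact_detached(lab, p)
  expect_equal(cls$intact_area_px, 400)
  expect_equal(cls$detached_area_px, 10)

  lab2 <- matrix(0L, 60, 40)
  lab2[5:24, 5:24] <- 1L; lab2[30:49, 5:24] <- 2L; lab2[55, 1:5] <- 3L
  cls2 <- classify_intact_detached(lab2, p)
  expect_setequal(cls2$intact, c(1L, 2L))
  expect_equal(cls2$detached, 3L)

  # no component reaches the cut: the largest one is still the organoid
  lab3 <- matrix(0L, 20, 20); lab3[1:3, 1:3] <- 1L; lab3[10, 10:11] <- 2L
  cls3 <- classify_intact_detached(lab3, p)
  expect_equal(cls3$intact, 1L)
  expect_error(classify_intact_detached(matrix(0L, 5, 5), p),
               "no above-background signal")
})

test_that("channel quantification floors the ratio and recovers truth", {
  p <- test_seg_params()
  img <- list(PODXL = matrix(20, 64, 64))
  img$PODXL[20:39, 20:39] <- 220       # body only, no detached
  q <- quantify_channel(img, "PODXL", 20, p)
  expect_true(q$ratio_floored)
  expect_equal(q$intact_detached_ratio, 400)

  out <- make_organoid_image(test_image_spec(seed = 21))
  q <- quantify_channel(out$image, "PODXL", 20, p)
  est_f <- q$intact_area_px / (q$intact_area_px + q$detached_area_px)
  expect_lt(abs(est_f - out$truth$intact_fraction[["PODXL"]]), 0.05)

  expect_error(quantify_channel(img, "PODXL", 20, p,
                                control_stats = list(mean_intensity = 0)),
               "control mean")
  qn <- quantify_channel(img, "PODXL", 20, p,
                         control_stats = list(mean_intensity = q$mean_intensity))
  expect_equal(qn$norm_intensity, qn$mean_intensity / q$mean_intensity)
})

test_that("area conservation holds exactly for every channel", {
  p <- test_seg_params()
  for (seed in 1:5) {
    out <- make_organoid_image(test_image_spec(seed = seed))
    for (ch in c("PODXL", "ECAD", "LTL")) {
      q <- quantify_channel(out$image, ch, 20, p)
      total <- sum(above_background_mask(out$image$channels[[ch]], 20, p))
      expect_identical(q$intact_area_px + q$detached_area_px, total)
    }
  }
})

test_that("an extra isolated detached object lowers the ratio only", {
  p <- test_seg_params()
  img <- matrix(20, 96, 96)
  img[40:59, 40:59] <- 220
  q0 <- quantify_channel(list(PODXL = img), "PODXL", 20, p)
  img[10:12, 10:12] <- 220             # one new 9-px detached speck
  q1 <- quantify_channel(list(PODXL = img), "PODXL", 20, p)
  expect_equal(q1$intact_area_px, q0$intact_area_px)
  expect_lt(q1$intact_detached_ratio, q0$intact_detached_ratio)
})

test_that("joint intensity scaling leaves masks unchanged", {
  set.seed(9)
  grid <- matrix(runif(64 * 64, 0, 100), 64, 64)
  for (cc in c(0.5, 3, 17)) {
    p1 <- segmentation_params(threshold_offset = 12, min_object_px = 4,
                              main_body_min_px = 50)
    p2 <- segmentation_params(threshold_offset = 12 * cc, min_object_px = 4,
                              main_body_min_px = 50)
    expect_identical(above_background_mask(grid, 30, p1),
                     above_background_mask(grid * cc, 30 * cc, p2))
  }
})

test_that("live/dead ratio is the ratio of above-background areas", {
  p <- segmentation_params(threshold_offset = 10, min_object_px = 4,
                           main_body_min_px = 50)
  green <- matrix(0, 100, 100); green[1:60, 1:50] <- 50   # 3000 px
  red <- matrix(0, 100, 100); red[1:30, 1:50] <- 50       # 1500 px
  ld <- live_dead_ratio(green, red, c(green = 0, red = 0), p)
  expect_equal(ld$ratio, 2)
  expect_false(ld$floored)

  ld2 <- live_dead_ratio(green, green, c(green = 0, red = 0), p)
  expect_equal(ld2$ratio, 1)

  ld3 <- live_dead_ratio(green, matrix(0, 100, 100), c(green = 0, red = 0), p)
  expect_true(ld3$floored)
  expect_equal(ld3$ratio, 3000)

  set.seed(2)
  g <- matrix(runif(900, 0, 40), 30, 30); r <- matrix(runif(900, 0, 40), 30, 30)
  ld4 <- live_dead_ratio(g, r, c(green = 5, red = 5), p)
  area <- function(x) {
    raw <- x > 15
    labs <- flood_fill_labels(raw, 8)
    sum(tabulate(labs[labs > 0])[tabulate(labs[labs > 0]) >= 4])
  }
  expect_equal(ld4$green_area_px, area(g))
  expect_equal(ld4$red_area_px, area(r))
})
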