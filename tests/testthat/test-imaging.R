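# Ratiometric imaging pipeline: calibration curve, background
# estimation, gating, anchoring, segmentation and record extraction.

std <- restus_calibration()

test_that("calibration curve: limits, midpoint, monotonicity, inverse", {
  expect_equal(voltage_to_ratio(-1e9, std), 2.86)
  expect_equal(voltage_to_ratio(1e9, std), 2.86 - 2.39)
  expect_equal(voltage_to_ratio(-31.8, std), 2.86 - 2.39 / 2)  # 1.665
  v <- seq(-120, 30, 1)
  expect_true(all(diff(voltage_to_ratio(v, std)) < 0))
  expect_equal(ratio_to_voltage(1.665, std), -31.8, tolerance = 1e-9)
  for (vv in c(-100, -50, 0, 30))
    expect_equal(ratio_to_voltage(voltage_to_ratio(vv, std), std), vv,
                 tolerance = 1e-9)
  expect_error(ratio_to_voltage(2.9, std), "gamut")
  expect_error(ratio_to_voltage(0.4, std), "gamut")
  expect_no_error(ratio_to_voltage(2.9, std, clamp = TRUE))
})

make_records <- function(n = 2000, background = 0, gain = 1,
                         v_mean = -50, v_sd = 8, seed = 1,
                         shot = 0) {
  cond <- data.frame(condition = "x", mean_mV = v_mean, sd_mV = v_sd)
  spec <- imaging_generator_spec(cond, dishes_per_condition = 1,
                                 cells_per_dish = n,
                                 gramicidin_dishes = 0,
                                 background = background, gain = gain,
                                 offset = 0, shot_scale = shot,
                                 seed = seed)
  gen_imaging_dataset(spec)
}

test_that("adaptive background recovers a planted green offset", {
  rec <- make_records(n = 8000, background = 60, shot = 1, seed = 21)
  est <- adaptive_background(rec)
  expect_lt(abs(est$background - 60) / 60, 0.05)
  # residual slope of median ratio vs f_red is ~0 after correction
  expect_lt(abs(est$slope), abs(kvmix:::.ratio_slope(rec, 0)))
})

test_that("zero-background data yields a near-zero estimate", {
  rec <- make_records(n = 4000, background = 0, shot = 1, seed = 22)
  est <- adaptive_background(rec)
  expect_lt(abs(est$background), 0.02 * median(rec$f_green))
})

test_that("background estimate is stable under record subsampling", {
  rec <- make_records(n = 6000, background = 60, shot = 1, seed = 23)
  full <- adaptive_background(rec)$background
  set.seed(1)
  half <- adaptive_background(rec[sample(nrow(rec), 3000), ])$background
  expect_lt(abs(full - half), 0.1 * full)
})

test_that("background estimation guards its preconditions", {
  rec <- make_records(n = 40)
  expect_error(adaptive_background(rec), "at least 50")
  rec2 <- make_records(n = 200, seed = 3)
  rec2$f_red <- 500 + (rec2$f_red - mean(rec2$f_red)) * 1e-3
  expect_warning(try(adaptive_background(rec2), silent = TRUE),
                 "spread")
})

test_that("f_red gating removes exactly the planted extremes", {
  rec <- make_records(n = 500, seed = 4)
  rec$f_red[1:5] <- 1e5                     # saturated cells
  out <- gate_records(rec, low = 0, high = 5e4)
  expect_equal(nrow(out), 495)
  expect_equal(attr(out, "gating_report")$removed_high, 5)
  all_in <- gate_records(rec, low = 0, high = Inf)
  expect_equal(nrow(all_in), nrow(rec))
  expect_error(gate_records(rec, low = 10, high = 5), "below")
})

test_that("gramicidin anchor: identity, averaging, and gain recovery", {
  r0 <- voltage_to_ratio(0, std)
  a <- gramicidin_anchor(r0, std)
  expect_equal(a$factor, 1)
  expect_equal(gramicidin_anchor(c(1.2, 1.6), std)$anchor, 1.4)
  # full pipeline with an instrument gain on the green channel
  cond <- data.frame(condition = c("ctrl", "chan"),
                     mean_mV = c(-40, -70), sd_mV = c(7, 7))
  spec <- imaging_generator_spec(cond, dishes_per_condition = 3,
                                 cells_per_dish = 800,
                                 gramicidin_dishes = 2, gain = 1.3,
                                 background = 40, offset = 100,
                                 seed = 31)
  rec <- gen_imaging_dataset(spec)
  gt <- attr(rec, "ground_truth")
  res <- analyze_imaging(rec,
                         gramicidin_dishes = grep("gramicidin",
                                                  unique(rec$dish_id),
                                                  value = TRUE),
                         offset_green = 100, offset_red = 100)
  per_cond <- tapply(res$summary$median_mV, res$summary$condition,
                     median)
  expect_lt(abs(per_cond[["ctrl"]] - gt$condition_median_mV[["ctrl"]]), 2)
  expect_lt(abs(per_cond[["chan"]] - gt$condition_median_mV[["chan"]]), 2)
})

test_that("dish summaries follow the median/mean conventions", {
  rec <- data.frame(dish_id = c("a", "b", "b", "b", "c", "c"),
                    voltage_mV = c(-50, -40, -42, -60, -30, -34),
                    ratio = 1)
  s <- summarize_dishes(rec)
  expect_equal(s$median_mV[s$dish_id == "a"], -50)
  expect_equal(s$mean_mV[s$dish_id == "a"], -50)
  expect_equal(s$median_mV[s$dish_id == "b"], -42)     # odd count
  expect_equal(s$median_mV[s$dish_id == "c"], -32)     # even: midpoint
  expect_equal(attr(s, "mean_of_medians_mV"), mean(c(-50, -42, -32)))
})

# -- segmentation ------------------------------------------------------

draw_disks <- function(px, centers, radius_px, value = 100) {
  img <- matrix(0, px, px)
  xx <- matrix(seq_len(px), px, px); yy <- t(xx)
  for (i in seq_len(nrow(centers))) {
    d2 <- (xx - centers[i, 1])^2 + (yy - centers[i, 2])^2
    img[d2 <= radius_px[i]^2] <- value
  }
  img
}

test_that("well-separated in-range nuclei are all found (recall = 1)", {
  px_size <- 0.73
  r_in <- sqrt(12 / pi) / px_size          # 12 um^2 target area
  centers <- as.matrix(expand.grid(seq(20, 180, 32), seq(20, 180, 32)))
  img <- draw_disks(200, centers, rep(r_in, nrow(centers)))
  cfg <- segmentation_config(rolling_ball_radius_um = 15,
                             pixel_size_um = px_size)
  rois <- segment_nuclei(img, cfg)
  expect_equal(nrow(rois$table), nrow(centers))   # precision = recall = 1
  expect_true(all(rois$table$area_um2 > 7.5 & rois$table$area_um2 < 19))
})

test_that("size gates exclude undersized and oversized particles", {
  px_size <- 0.73
  r_ok <- sqrt(12 / pi) / px_size
  r_small <- sqrt(4 / pi) / px_size        # < 7.5 um^2
  r_big <- sqrt(30 / pi) / px_size         # > 19 um^2
  centers <- as.matrix(expand.grid(seq(25, 175, 50), seq(25, 175, 50)))
  radii <- rep(c(r_ok, r_small, r_big, r_ok), length.out = nrow(centers))
  img <- draw_disks(200, centers, radii)
  cfg <- segmentation_config(rolling_ball_radius_um = 15,
                             pixel_size_um = px_size)
  rois <- segment_nuclei(img, cfg)
  expect_equal(nrow(rois$table), sum(abs(radii - r_ok) < 1e-9))
})

test_that("blank images give zero ROIs, border particles are dropped", {
  cfg <- segmentation_config(rolling_ball_radius_um = 15,
                             pixel_size_um = 0.73)
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64), cfg)$table), 0)
  r <- sqrt(12 / pi) / 0.73
  img <- draw_disks(100, rbind(c(2, 50), c(50, 50)), c(r, r))
  rois <- segment_nuclei(img, cfg)
  expect_equal(nrow(rois$table), 1)        # border-intersecting excluded
  cfg2 <- segmentation_config(rolling_ball_radius_um = 15,
                              pixel_size_um = 0.73,
                              exclude_border = FALSE)
  rois2 <- segment_nuclei(img, cfg2)
  expect_true(any(rois2$table$border_flag))
})

test_that("record extraction reads planted intensities and frame 4", {
  img <- gen_imaging_dataset(
    imaging_generator_spec(data.frame(condition = "x", mean_mV = -50,
                                      sd_mV = 6), seed = 41),
    level = "image", image_px = 192, cells_per_position = 6)
  p <- img$positions[[1]]
  cfg <- segmentation_config(rolling_ball_radius_um = 15,
                             pixel_size_um = img$pixel_size_um)
  rois <- segment_nuclei(p$blue, cfg)
  expect_equal(nrow(rois$table), 6)
  rec <- extract_cell_records(rois, p$green, p$red, p$blue,
                              dish_id = "d1")
  # match extracted cells to planted truth by nearest centroid
  truth <- img$truth
  idx <- vapply(seq_len(nrow(rec)), function(i)
    which.min((truth$x - rec$centroid_x[i])^2 +
                (truth$y - rec$centroid_y[i])^2), integer(1))
  expect_equal(rec$f_red, truth$f_red[idx], tolerance = 1e-6)
  # frame 4 is within 2% of the photoswitching plateau; frame 1 is not
  expect_equal(rec$f_green, truth$f_green_plateau[idx],
               tolerance = 0.02)
  rec1 <- extract_cell_records(rois, p$green[c(1, 1, 1, 1)], p$red,
                               p$blue)
  expect_true(all(rec1$f_green < 0.85 * truth$f_green_plateau[idx]))
  expect_error(extract_cell_records(rois, p$green[1:3], p$red, p$blue),
               "4 green frames")
})
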