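unit_calibration <- function() {
  calibrate(new_boxes(c("200", "30"), x_center = 20,
                      y_center = c(40, 210), width = 30, height = 14))
}

test_that("calibration anchors and interpolates linearly", {
  cal <- unit_calibration()
  expect_equal(cal$mmhg_per_pixel, 1)
  at <- function(y) value_of(new_boxes("arrow", 10, y, 5, 7), cal)$mmHg
  expect_equal(at(40), 200)
  expect_equal(at(210), 30)
  expect_equal(at(125), 115)  # midpoint of the anchors

  # anchors 170 px apart, 17 px below the 200 anchor -> 183 mmHg
  expect_equal(at(57), 183)

  # above the 200 anchor: extrapolated and flagged
  v <- value_of(new_boxes("arrow", 10, 30, 5, 7), cal)
  expect_equal(v$mmHg, 210)
  expect_true(v$out_of_legend)
})

test_that("missing or duplicated legend markers are errors", {
  expect_error(calibrate(new_boxes("200", 10, 40, 30, 14)), "'30'")
  dup <- new_boxes(c("200", "200", "30"), 10, c(40, 42, 210), 30, 14)
  expect_error(calibrate(dup), "'200' detected 2")
  upside <- new_boxes(c("200", "30"), 10, c(210, 40), 30, 14)
  expect_error(calibrate(upside), "below")
})

test_that("the flip trick restores diastolic y and is an involution", {
  H <- 100
  sec <- matrix(255, H, 120)
  # one down-arrow (systolic) at y 30, one up-arrow (diastolic) at y 70
  sys_truth <- new_boxes("arrow", 60, 30, 5, 7)
  dia_truth <- new_boxes("arrow", 60, 70, 5, 7)
  det <- fixture_detector(sys_truth, flipped_truth = dia_truth,
                          frame_height = H)
  res <- detect_arrows(sec, det, tile_grid(64, 64))
  expect_equal(res$systolic$y_center, 30)
  expect_equal(res$diastolic$y_center, 70)

  # fixture arrow reported at y 10 in a flipped frame of height 100
  det2 <- fixture_detector(new_boxes("arrow", 60, 90, 5, 7),
                           flipped_truth = new_boxes("arrow", 60, 90, 5, 7),
                           frame_height = H)
  flipped_view <- det2$detect(flip_vertical(sec), orientation = "flipped")
  expect_equal(flipped_view$y_center, 10)

  expect_identical(flip_vertical(flip_vertical(sec)), sec)
})

test_that("timestamp pairing honors the 1% width bound", {
  cal <- unit_calibration()
  mk <- function(xs, ys = 100) {
    value_of(new_boxes("arrow", xs, ys, 5, 7), cal)
  }
  # dx = 2 on width 1000: paired, one reading at t = 0
  r <- assign_timestamps(mk(100), mk(102), width = 1000)
  expect_equal(nrow(r), 1)
  expect_equal(r$t_minutes, 0)
  expect_false(is.na(r$systolic) || is.na(r$diastolic))

  # dx = 15 > 10: two separate incomplete readings
  r2 <- assign_timestamps(mk(100), mk(115), width = 1000)
  expect_equal(nrow(r2), 2)
  expect_true(is.na(r2$diastolic[1]) && is.na(r2$systolic[2]))
})

test_that("timestamp gaps follow the 1.8% width dichotomy", {
  cal <- unit_calibration()
  mk <- function(xs) value_of(new_boxes("arrow", xs, 100, 5, 7), cal)
  # reading x-gaps 12 (<= 18) and 20 (> 18) on width 1000 -> t = 0, 5, 15
  r <- assign_timestamps(mk(c(100, 112, 132)), mk(c(100, 112, 132)),
                         width = 1000)
  expect_equal(r$t_minutes, c(0, 5, 15))
})

test_that("timestamps start at zero, never decrease, and are multiples of 5", {
  cal <- unit_calibration()
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(1:15, 1)
    xs <- sort(runif(n, 0, 500))
    sys <- value_of(new_boxes("arrow", xs, 100, 5, 7), cal)
    dia <- value_of(new_boxes("arrow", xs + runif(n, -2, 2), 140, 5, 7), cal)
    r <- assign_timestamps(sys, dia, width = 540)
    expect_equal(r$t_minutes[1], 0)
    expect_true(all(diff(r$t_minutes) >= 0))
    expect_true(all(r$t_minutes %% 5 == 0))
  }
  empty <- assign_timestamps(new_boxes(), new_boxes(), width = 540)
  expect_equal(nrow(empty), 0)
})

test_that("bp_mae is the mean absolute difference of matched lists", {
  expect_equal(bp_mae(c(120, 80, 130), c(120, 80, 130)), 0)
  expect_equal(bp_mae(120, 118), 2)
  expect_equal(bp_mae(c(120, 80, 130), c(118, 82, 130)), 4 / 3)
  expect_error(bp_mae(1:3, 1:2), "equal length")
})

test_that("zero-noise synthetic arrows recover their mmHg exactly", {
  ch <- render_chart(synth_spec(seed = 13L))
  truth <- ch$truth
  sec_tbl <- truth$layout$sections
  bp_sec <- sec_tbl[sec_tbl$name == "blood_pressure", ]
  det <- fixture_detector(
    truth$bp$systolic[, names(new_boxes())],
    flipped_truth = truth$bp$diastolic[, names(new_boxes())],
    frame_height = bp_sec$height
  )
  sec_img <- crop_sections(ch$image, bp_sec)$blood_pressure$image
  arrows <- detect_arrows(sec_img, det)
  legend_det <- fixture_detector(truth$bp$legend)
  cal <- calibrate(legend_det$detect(sec_img))
  sys <- value_of(dplyr::arrange(arrows$systolic, x_center), cal)
  dia <- value_of(dplyr::arrange(arrows$diastolic, x_center), cal)
  expect_equal(sys$mmHg, truth$bp_truth$systolic,
               tolerance = 0.5 * cal$mmhg_per_pixel)
  expect_equal(dia$mmHg, truth$bp_truth$diastolic,
               tolerance = 0.5 * cal$mmhg_per_pixel)
})

test_that("1.5 px jitter at 1 px per mmHg keeps MAE within 1.5 mmHg", {
  cal <- unit_calibration()
  set.seed(41)
  n <- 600
  truth_v <- sample(40:190, n, replace = TRUE)
  y <- cal$y_200 + (200 - truth_v) + rnorm(n, 0, 1.5)
  vals <- value_of(new_boxes("arrow", x_center = seq_len(n), y_center = y,
                             width = 5, height = 7), cal)$mmHg
  expect_lte(mean(abs(vals - truth_v)), 1.5)
})
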