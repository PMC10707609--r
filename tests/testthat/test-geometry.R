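test_that("Kasa fit is exact on analytic circle points", {
  pts <- circle_points(320.3, 200.7, 30.5, n = 20)
  fit <- kasa_from_points(pts$x, pts$y)
  expect_equal(fit$cx, 320.3, tolerance = 1e-10)
  expect_equal(fit$cy, 200.7, tolerance = 1e-10)
  expect_equal(fit$r, 30.5, tolerance = 1e-10)
  expect_lt(fit$rms, 1e-9)
})

test_that("Kasa fit matches the brute-force grid-search oracle", {
  pts <- circle_points(50.2, 60.8, 20.4, n = 24)
  fit <- kasa_from_points(pts$x, pts$y)
  oracle <- brute_circle_fit(pts$x, pts$y, center0 = c(50.2, 60.8), r0 = 20.4,
                             half_width = 0.5, step = 0.05)
  expect_lt(abs(fit$cx - oracle[["cx"]]), 0.05)
  expect_lt(abs(fit$cy - oracle[["cy"]]), 0.05)
  expect_lt(abs(fit$r - oracle[["r"]]), 0.05)
})

test_that("rasterized pupil disks are fitted to sub-pixel accuracy", {
  m <- disk_mask(400, 640, center_row = 200, center_col = 320, radius = 24)
  fit <- fit_pupil_circle(m)
  expect_lt(abs(fit$center_row_px - 200), 0.5)
  expect_lt(abs(fit$center_col_px - 320), 0.5)
  expect_lt(abs(fit$radius_px - 24), 0.5)
})

test_that("lid occlusion of the upper pupil does not bias the fit", {
  m <- disk_mask(400, 640, center_row = 200, center_col = 320, radius = 24)
  m[1:190, ] <- 0L                       # lid covers the top ~30% of the disk
  fit <- fit_pupil_circle(m)
  expect_lt(abs(fit$center_col_px - 320), 1)
  expect_lt(abs(fit$center_row_px - 200), 1)
  expect_gt(fit$chord_excluded, 0)
})

test_that("insufficient pupil boundary is an explicit error", {
  m <- matrix(2L, 20, 20); m[10, 10] <- 3L
  expect_error(fit_pupil_circle(m), class = "mrdeye_insufficient_boundary")
  expect_error(fit_pupil_circle(matrix(1L, 10, 10)),
               class = "mrdeye_no_pupil")
})

test_that("lid-margin localization follows the background-run rule", {
  m <- matrix(2L, 400, 100)
  m[1:164, ] <- 0L                         # margin between rows 164 and 165
  res <- find_upper_lid_margin(m, c(200, 50))
  expect_lte(abs((200 - res$lid_margin_row_px) - 36), 0.5)

  # a single-row background speckle above the centre is skipped (k = 3)
  m2 <- m; m2[190, 50] <- 0L
  res2 <- find_upper_lid_margin(m2, c(200, 50))
  expect_equal(res2$lid_margin_row_px, res$lid_margin_row_px)

  # lid drawn over the pupil centre raises the flag, not an error
  m3 <- m; m3[200, 50] <- 0L
  res3 <- find_upper_lid_margin(m3, c(200, 50))
  expect_true(is.na(res3$lid_margin_row_px))
  expect_identical(res3$flags, "lid_covers_pupil_center")

  # no background anywhere above the centre: margin not found
  m4 <- matrix(2L, 400, 100)
  expect_error(find_upper_lid_margin(m4, c(200, 50)),
               class = "mrdeye_margin_not_found")
  expect_error(find_upper_lid_margin(m, c(2000, 50)),
               class = "mrdeye_out_of_bounds")
})

test_that("calibration-dot detection recovers the render scale", {
  r <- render_eye(small_spec(noise_sd = 0))
  cal <- detect_calibration_dot(r$image, nominal_mm = 5)
  expect_lt(abs(cal$px_per_mm - 12), 0.2)
  expect_equal(cal$px_per_mm, cal$dot_diameter_px / 5)

  # no dot
  r0 <- render_eye(small_spec(dot = NULL))
  expect_error(detect_calibration_dot(r0$image),
               class = "mrdeye_calibration_failed")

  # two dots: failure reports the candidate count
  img <- matrix(0.5, 300, 300)
  rr <- matrix(seq_len(300), 300, 300)
  cc <- t(rr)
  img[(rr - 80)^2 + (cc - 80)^2 <= 20^2] <- 1
  img[(rr - 220)^2 + (cc - 220)^2 <= 20^2] <- 1
  err <- tryCatch(detect_calibration_dot(img), error = identity)
  expect_s3_class(err, "mrdeye_calibration_failed")
  expect_match(conditionMessage(err), "2 candidate")
})

test_that("MRD1 arithmetic and sign convention", {
  expect_equal(compute_mrd1(200, 164, 12), 3.0)
  expect_equal(compute_mrd1(200, 200, 12), 0.0)
  expect_equal(compute_mrd1(200, 212, 12), -1.0)
  expect_error(compute_mrd1(200, 164, 0))
})

test_that("measure_image composes the pipeline and captures failures", {
  r <- render_eye(small_spec(upper_lid = lid_curve(3.0, 0.06), noise_sd = 0))
  res <- measure_image(r$image)
  expect_true(res$ok)
  expect_lt(abs(res$mrd1_mm - 3.0), 1 / 12)
  expect_identical(res$scale_source, "dot")
  expect_equal(res$mrd1_mm, res$mrd1_px / res$px_per_mm)

  # injected truth mask with a known scale: bypasses segmentation and dot
  res2 <- measure_image(r$image, mask = r$truth$truth_mask,
                        config = measure_config(px_per_mm = 12))
  expect_true(res2$ok)
  expect_identical(res2$scale_source, "config")
  expect_lt(abs(res2$mrd1_mm - 3.0), 1 / 12)

  # segmentation failure becomes a structured record, not an error
  res3 <- measure_image(matrix(0.5, 120, 120))
  expect_false(res3$ok)
  expect_match(res3$qc_flags, "pupil_not_found")
  expect_true(is.na(res3$mrd1_mm))
})

test_that("a lid descending past the pupil centre is flagged (MRD1 <= 0 case)", {
  # visible pupil crescent whose fitted centre lies under the lid
  m <- matrix(0L, 300, 300)
  m[240:280, ] <- 1L                                   # narrow aperture slit
  rr <- matrix(seq_len(300), 300, 300); cc <- t(rr)
  m[(rr - 250)^2 + (cc - 150)^2 <= 60^2 & m > 0] <- 2L
  m[(rr - 230)^2 + (cc - 150)^2 <= 24^2 & m > 0] <- 3L
  res <- measure_image(matrix(0.5, 300, 300), mask = m,
                       config = measure_config(px_per_mm = 12))
  expect_false(res$ok)
  expect_match(res$qc_flags, "lid_covers_pupil_center")
})

test_that("MRD1 estimates are scale-equivariant across render resolutions", {
  est <- vapply(c(8, 12, 16), function(s) {
    r <- render_eye(eye_spec(image_height_px = 360, image_width_px = 480,
                             px_per_mm = s, noise_sd = 0))
    measure_image(r$image)$mrd1_mm
  }, numeric(1))
  expect_lt(max(est) - min(est), 2 / 8)
})

test_that("whole-pixel scene translation leaves MRD1 unchanged", {
  r0 <- render_eye(small_spec(noise_sd = 0))
  r1 <- render_eye(small_spec(noise_sd = 0,
                              pupil_center_mm = c(5 / 12, -3 / 12)))
  m0 <- measure_image(r0$image)
  m1 <- measure_image(r1$image)
  expect_lt(abs(m0$mrd1_mm - m1$mrd1_mm), 1e-6)
})
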