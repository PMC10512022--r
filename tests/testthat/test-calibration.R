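# sign detection, spatial scale, color correction

test_that("sign corners, skew and scale are recovered from rendered scenes", {
  cfg <- test_config()
  sc <- std_scene("sign", seed = 42)
  det <- detect_sign(sc$image, cfg)
  expect_lte(max(abs(det$corners - sc$truth$sign_corners)), 1)
  expect_gte(det$border_score, 0.7)
  expect_length(det$flags, 0L)
  sc_rec <- spatial_scale(det, c(cfg$sign$width_cm, cfg$sign$height_cm))
  expect_lt(abs(sc_rec / sc$truth$scale - 1), 0.01)
  # no sign in the "naked" side view
  expect_error(detect_sign(std_scene("side", seed = 42)$image, cfg), "sign not found")
  # 10-degree skew is reported and scale stays within 1 percent
  # (full-resolution render: corner rounding dominates at coarse scales)
  cfg_f <- full_config()
  sk <- generate_scene(scene_params(pose = "sign", seed = 5,
                                    defects = "skewed_sign"), cfg_f)
  det_s <- detect_sign(sk$image, cfg_f)
  expect_equal(det_s$skew_deg, 10, tolerance = 0.1)  # +- 1 degree
  expect_lt(abs(spatial_scale(det_s, c(cfg_f$sign$width_cm, cfg_f$sign$height_cm)) /
                  sk$truth$scale - 1), 0.01)
})

test_that("spatial scale is the mean of width- and height-based ratios", {
  det <- structure(list(corners = rbind(TL = c(100, 100), TR = c(100, 499),
                                        BR = c(399, 499), BL = c(399, 100))),
                   class = "sign_detection")
  # 40 cm over 400 px and 30 cm over 300 px -> 0.1 cm/px either way
  expect_equal(spatial_scale(det, c(40, 30)), 0.1)
  # width- and height-based estimates agree on an unskewed render
  cfg <- test_config()
  sc <- std_scene("sign", seed = 42)
  co <- detect_sign(sc$image, cfg)$corners
  w_est <- cfg$sign$width_cm / (sqrt(sum((co["TR", ] - co["TL", ])^2)) + 1)
  h_est <- cfg$sign$height_cm / (sqrt(sum((co["BL", ] - co["TL", ])^2)) + 1)
  expect_lt(abs(w_est / h_est - 1), 0.005)
  # degenerate quadrilateral errors
  bad <- structure(list(corners = rbind(TL = c(1, 1), TR = c(1, 2),
                                        BR = c(2, 2), BL = c(2, 1))),
                   class = "sign_detection")
  expect_error(spatial_scale(bad, c(40, 30)), "degenerate")
})

test_that("color transform is identity on perfect measurements and inverts gains", {
  cfg <- full_config()
  refs <- rbind(cfg$sign$ref_border, cfg$sign$ref_red,
                cfg$sign$ref_green, cfg$sign$ref_blue)
  det0 <- list(border_color = refs[1, ], block_colors = refs[2:4, ])
  tf0 <- estimate_color_transform(det0, refs)
  expect_equal(tf0$M, diag(3), tolerance = 1e-9)
  expect_equal(tf0$residual, 0, tolerance = 1e-9)
  # global 0.8x gain: recovered within 2 percent, blocks corrected within 2 units
  sc <- generate_scene(scene_params(pose = "sign", seed = 21,
                                    defects = "lighting_shift",
                                    lighting_gain = 0.8), test_config())
  det <- detect_sign(sc$image, test_config())
  tf <- estimate_color_transform(det, refs)
  expect_lt(abs(1 / mean(diag(tf$M)) / 0.8 - 1), 0.02)
  corrected <- apply_color_transform(det$block_colors, tf)
  expect_lt(max(abs(corrected - refs[2:4, ])), 2)
  # held-out grey patch corrected to within 3 units
  grey <- matrix(round(c(120, 120, 120) * 0.8), 1)
  expect_lt(max(abs(apply_color_transform(grey, tf) - c(120, 120, 120))), 3)
  # rank-deficient measurements error out
  det_bad <- list(border_color = c(0, 0, 0),
                  block_colors = rbind(c(100, 0, 0), c(100, 0, 0), c(0, 0, 100)))
  expect_error(estimate_color_transform(det_bad, refs), "rank")
})

test_that("the fitted transform reduces block residual versus identity under lighting shifts", {
  cfg <- test_config()
  refs <- rbind(cfg$sign$ref_border, cfg$sign$ref_red,
                cfg$sign$ref_green, cfg$sign$ref_blue)
  for (g in c(0.75, 0.9, 1.15)) {
    sc <- generate_scene(scene_params(pose = "sign", seed = 33,
                                      defects = "lighting_shift",
                                      lighting_gain = g), cfg)
    det <- detect_sign(sc$image, cfg)
    tf <- estimate_color_transform(det, refs)
    measured <- rbind(det$border_color, det$block_colors)
    res_id <- mean(abs(measured - refs))
    expect_lt(tf$residual, res_id)
  }
})

test_that("calibrate_from_sign bundles scale and transform with provenance", {
  cfg <- test_config()
  sc <- std_scene("sign", seed = 42)
  cal <- calibrate_from_sign(sc$image, cfg)
  expect_s3_class(cal, "calibration_result")
  expect_equal(cal$source_pose, "sign")
  expect_gt(cal$scale, 0)
  expect_equal(cal$residual, 0, tolerance = 1e-6)
})
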