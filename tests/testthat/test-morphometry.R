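# calibrated body measures and their oracles

test_that("ground row is recovered and translation-equivariant", {
  sc <- std_scene("side", seed = 42)
  g <- ground_row(sc$truth$mask)
  expect_lte(abs(g - sc$truth$ground_row), 2)
  m <- sc$truth$mask
  shifted <- rbind(matrix(FALSE, 10, ncol(m)), m[1:(nrow(m) - 10), ])
  expect_equal(ground_row(shifted), g + 10L)
  # a mask with no resolvable legs errors
  blob <- matrix(FALSE, 100, 100); blob[40:60, 30:70] <- TRUE
  expect_error(ground_row(blob), "legs")
})

test_that("height at withers recovers truth, scales linearly and preserves order", {
  cfg <- test_config()
  sc <- std_scene("side", seed = 42)   # HW = 60
  mk <- segment_scene(sc, cfg)
  hw <- height_at_withers(mk, sc$truth$scale, bands = cfg$bands)
  expect_lt(abs(hw$HW - 60) / 60, 0.02)
  hw2 <- height_at_withers(mk, 2 * sc$truth$scale, bands = cfg$bands)
  expect_equal(hw2$HW, 2 * hw$HW)
  tall <- generate_scene(scene_params(hw = 75, pose = "side", seed = 42), cfg)
  hw3 <- height_at_withers(segment_scene(tall, cfg), tall$truth$scale,
                           bands = cfg$bands)
  expect_gt(hw3$HW, hw$HW)
})

test_that("raised heads are excluded from the topline by the neck inflection", {
  cfg <- test_config()
  sc <- generate_scene(scene_params(hw = 60, bl = 70, pose = "side", seed = 8,
                                    head_y_frac = 1.05), cfg)
  mk <- segment_scene(sc, cfg)
  hw <- height_at_withers(mk, sc$truth$scale, bands = cfg$bands)
  expect_lt(abs(hw$HW - 60) / 60, 0.02)
})

test_that("body length is mirror-symmetric and head-independent", {
  cfg <- test_config()
  sc <- std_scene("side", seed = 42)   # BL = 70
  mk <- segment_scene(sc, cfg)
  bl <- body_length(mk, sc$truth$scale, bands = cfg$bands)
  expect_lt(abs(bl$BL - 70) / 70, 0.02)
  mirrored <- mk$mask[, rev(seq_len(ncol(mk$mask)))]
  bl_m <- body_length(mirrored, sc$truth$scale, bands = cfg$bands)
  expect_equal(bl_m$BL, bl$BL, tolerance = 1e-9)
  expect_true("MIRRORED" %in% bl_m$flags)
  # a long raised neck must not stretch the measured length
  ln <- generate_scene(scene_params(hw = 60, bl = 70, pose = "side", seed = 8,
                                    head_y_frac = 1.05), cfg)
  bl_ln <- body_length(segment_scene(ln, cfg), ln$truth$scale, bands = cfg$bands)
  expect_lt(abs(bl_ln$BL - 70) / 70, 0.02)
})

test_that("chest depth and width recover truth; dilation grows width by its diameter", {
  cfg <- test_config()
  sc <- std_scene("side", seed = 42)   # depth = 30
  dp <- chest_depth(segment_scene(sc, cfg), sc$truth$scale, bands = cfg$bands)
  expect_lt(abs(dp - 30) / 30, 0.02)
  rr <- std_scene("rear", seed = 42)   # width = 20
  mk_r <- segment_scene(rr, cfg)
  cw <- chest_width(mk_r, rr$truth$scale, bands = cfg$bands)
  expect_lt(abs(cw - 20) / 20, 0.02)
  dil <- goatpheno:::dilate_mask(mk_r$mask, 2)
  cw_d <- chest_width(dil, rr$truth$scale, bands = cfg$bands)
  expect_equal(cw_d - cw, 4 * rr$truth$scale, tolerance = 1e-9)
})

test_that("chest girth matches the circle limit and numerical quadrature", {
  # circle: perimeter pi * d
  expect_equal(chest_girth(25, 25), pi * 25, tolerance = 1e-9)
  # numerical arc length of the ellipse as the independent oracle
  ellipse_perimeter_quad <- function(a, b) {
    f <- function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2)
    4 * stats::integrate(f, 0, pi / 2, rel.tol = 1e-12)$value
  }
  for (ratio in c(1, 1.3, 1.7, 2, 2.5, 3)) {
    d <- 30; w <- d / ratio
    expect_lt(abs(chest_girth(d, w) / ellipse_perimeter_quad(d / 2, w / 2) - 1),
              0.001, label = paste("ratio", ratio))
  }
  # strict monotonicity in both arguments
  expect_gt(chest_girth(31, 20), chest_girth(30, 20))
  expect_gt(chest_girth(30, 21), chest_girth(30, 20))
  expect_error(chest_girth(0, 20), "positive")
})

test_that("weight prediction honors its formula contracts", {
  m <- body_measures(HW = 60, BL = 70, chest_depth = 30, chest_width = 20,
                     CG = chest_girth(30, 20))
  # degenerate coefficients: BW passes CG through
  pw <- predict_weight(m, list(formula = "power", a = 1, p_cg = 1, p_bl = 0, p_hw = 0))
  expect_equal(pw$BW, m$CG)
  # doubling all linear measures under a cubic power law scales BW by 8
  m2 <- body_measures(HW = 120, BL = 140, chest_depth = 60, chest_width = 40,
                      CG = 2 * m$CG)
  f3 <- list(formula = "power", a = 1e-4, p_cg = 2, p_bl = 1, p_hw = 0)
  expect_equal(predict_weight(m2, f3)$BW / predict_weight(m, f3)$BW, 8)
  # k solved so a reference triple maps to 40 kg
  k <- m$CG^2 * m$BL / 40
  expect_equal(predict_weight(m, list(formula = "cg2bl", k = k))$BW, 40)
  # missing required measure: absent BW plus a flag
  m3 <- body_measures(HW = 60)
  pw3 <- predict_weight(m3, list(formula = "cg2bl", k = 10838))
  expect_true(is.na(pw3$BW))
  expect_gt(length(pw3$flags), 0)
})

test_that("validation correlations match a textbook two-pass Pearson", {
  d <- data.frame(sample_id = sprintf("A%02d", 1:20), HW = NA, BL = NA)
  set.seed(9)
  d$HW <- runif(20, 40, 90); d$BL <- runif(20, 50, 100)
  # identical tables: r = 1
  expect_equal(validate_measures(d, d)$r, c(1, 1))
  # affine transform leaves r = 1
  m <- d; m$HW <- 2 * d$HW + 5; m$BL <- -3 * d$BL + 1
  expect_equal(abs(validate_measures(d, m)$r), c(1, 1))
  # two-pass oracle on noisy vectors, to 1e-12
  two_pass <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  m2 <- d; m2$HW <- d$HW + rnorm(20, 0, 3); m2$BL <- d$BL + rnorm(20, 0, 4)
  got <- validate_measures(d, m2)
  expect_equal(got$r[1], two_pass(d$HW, m2$HW), tolerance = 1e-12)
  expect_equal(got$r[2], two_pass(d$BL, m2$BL), tolerance = 1e-12)
  # zero variance: undefined r reported as NA
  z <- d; z$HW <- 50
  expect_true(is.na(validate_measures(z, d)$r[1]))
  expect_equal(validate_measures(d, m2)$n, c(20L, 20L))
})

test_that("measures are translation-invariant", {
  cfg <- test_config()
  sc <- std_scene("side", seed = 42)
  mk <- segment_scene(sc, cfg)
  m <- mk$mask
  pad <- matrix(FALSE, nrow(m), ncol(m))
  shifted <- pad
  shifted[11:nrow(m), 6:ncol(m)] <- m[1:(nrow(m) - 10), 1:(ncol(m) - 5)]
  s0 <- sc$truth$scale
  expect_equal(height_at_withers(shifted, s0, bands = cfg$bands)$HW,
               height_at_withers(m, s0, bands = cfg$bands)$HW)
  expect_equal(body_length(shifted, s0, bands = cfg$bands)$BL,
               body_length(m, s0, bands = cfg$bands)$BL)
  expect_equal(chest_depth(shifted, s0, bands = cfg$bands),
               chest_depth(m, s0, bands = cfg$bands))
})

test_that("cohort median recovery error stays within 2 percent per measure", {
  co <- cached_cohort()
  med <- function(a, b) stats::median(abs(a - b) / b, na.rm = TRUE)
  expect_lte(med(co$hw_rec, co$hw_true), 0.02)
  expect_lte(med(co$bl_rec, co$bl_true), 0.02)
  expect_lte(med(co$depth_rec, co$depth_true), 0.02)
  expect_lte(med(co$width_rec, co$width_true), 0.02)
})
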