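# coat color clustering and pattern summary

test_that("a solid coat yields one full-fraction cluster", {
  cfg <- test_config()
  sc <- std_scene("side", seed = 21)
  mk <- segment_scene(sc, cfg, refine = FALSE)
  cs <- coat_colors(sc$image, mk, identity_transform(), 3, cfg)
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(unname(cs$clusters[1, "fraction"]), 1)
  expect_equal(cs$pattern_class, "solid")
  expect_lt(max(abs(cs$clusters[1, 1:3] - c(196, 160, 110))), 2)
})

test_that("a 60/40 two-tone coat is recovered as patched with matching fractions", {
  cfg <- test_config()
  sc <- generate_scene(scene_params(pose = "side", seed = 22,
                                    coat_colors = list(c(196, 160, 110), c(45, 38, 34)),
                                    pattern = "patched",
                                    pattern_fracs = c(0.6, 0.4)), cfg)
  mk <- segment_scene(sc, cfg, refine = FALSE)
  cs <- coat_colors(sc$image, mk, identity_transform(), 3, cfg)
  expect_equal(nrow(cs$clusters), 2L)
  expect_equal(unname(cs$clusters[, "fraction"]), c(0.6, 0.4), tolerance = 0.05)
  expect_equal(cs$pattern_class, "patched")
  expect_equal(sum(cs$clusters[, "fraction"]), 1, tolerance = 1e-6)
  # fixed seed: bit-for-bit reproducible
  cs2 <- coat_colors(sc$image, mk, identity_transform(), 3, cfg)
  expect_identical(cs$clusters, cs2$clusters)
  expect_identical(cs$pattern_map, cs2$pattern_map)
})

test_that("calibration brings lit and unlit coats closer than no calibration", {
  cfg <- test_config()
  refs <- rbind(cfg$sign$ref_border, cfg$sign$ref_red,
                cfg$sign$ref_green, cfg$sign$ref_blue)
  base <- std_scene("side", seed = 23)
  mk <- segment_scene(base, cfg, refine = FALSE)
  clean <- coat_colors(base$image, mk, identity_transform(), 3, cfg)
  # same scene under 0.8x lighting; transform from a matching sign scene
  dim_img <- pmax(pmin(round(base$image$pixels * 0.8), 255), 0)
  sgn <- generate_scene(scene_params(pose = "sign", seed = 23,
                                     defects = "lighting_shift",
                                     lighting_gain = 0.8), cfg)
  tf <- estimate_color_transform(detect_sign(sgn$image, cfg), refs)
  corrected <- coat_colors(dim_img, mk, tf, 3, cfg)
  uncorrected <- coat_colors(dim_img, mk, identity_transform(), 3, cfg)
  d_corr <- sqrt(sum((corrected$clusters[1, 1:3] - clean$clusters[1, 1:3])^2))
  d_raw <- sqrt(sum((uncorrected$clusters[1, 1:3] - clean$clusters[1, 1:3])^2))
  expect_lt(d_corr, 3)
  expect_lt(d_corr, d_raw)
})

test_that("small masks are rejected and the pattern map run-length encodes", {
  cfg <- test_config()
  img <- array(120, c(100, 100, 3))
  tiny <- matrix(FALSE, 100, 100); tiny[1:10, 1:10] <- TRUE
  expect_error(coat_colors(img, tiny, identity_transform(), 3, cfg), "insufficient")
  pm <- rbind(c(0L, 1L, 1L, 2L), c(2L, 2L, 0L, 0L))
  rl <- pattern_rle(pm)
  expect_equal(rl$length[rl$row == 1 & rl$label == 1], 2L)
  expect_equal(sum(rl$length), sum(pm > 0))
})
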