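# FAMACHA scoring and tooth-age classing

test_that("famacha matches exact reference colors and breaks ties anemic-ward", {
  cfg <- full_config()
  refs <- cfg$famacha$refs
  sc <- generate_eye_scene(3, seed = 5, noise_sd = 0, config = cfg)
  fr <- famacha_score(sc$image, identity_transform(), refs, cfg)
  expect_equal(fr$category, 3)
  expect_equal(min(fr$distances), 0, tolerance = 1e-6)
  # ROI color exactly midway between refs 1 and 2 -> category 2
  img <- array(0, c(200, 200, 3))
  for (ch in 1:3) img[, , ch] <- 120   # neutral surround, outside the gate
  mid <- (refs[1, ] + refs[2, ]) / 2
  for (ch in 1:3) img[60:140, 60:140, ch] <- mid[ch]
  fr2 <- famacha_score(img, identity_transform(), refs, cfg)
  expect_equal(fr2$category, 2)
  # no pink region anywhere -> conjunctiva not found
  flat <- array(110, c(100, 100, 3))
  expect_error(famacha_score(flat, identity_transform(), refs, cfg), "conjunctiva")
})

test_that("famacha is accurate under noise and monotone along the reference ramp", {
  cfg <- full_config()
  sim <- famacha_simulation(n_per_cat = 6, seed = 2, noise_sd = 4, config = cfg)
  expect_gte(sim$accuracy, 0.95)
  # sweep along the piecewise-linear reference path: categories never decrease
  refs <- cfg$famacha$refs
  make_eye <- function(color) {
    img <- array(120, c(120, 160, 3))
    for (ch in 1:3) img[40:80, 50:110, ch] <- color[ch]
    img
  }
  cats <- integer()
  for (seg in 1:4) {
    for (t in seq(0, 1, by = 0.25)) {
      col <- (1 - t) * refs[seg, ] + t * refs[seg + 1, ]
      cats <- c(cats, famacha_score(make_eye(col), identity_transform(),
                                    refs, cfg)$category)
    }
  }
  expect_true(all(diff(cats) >= 0))
  expect_equal(cats[1], 1L)
  expect_equal(tail(cats, 1), 5L)
})

test_that("famacha is invariant to lighting the color transform corrects", {
  cfg <- full_config()
  refs <- rbind(cfg$sign$ref_border, cfg$sign$ref_red,
                cfg$sign$ref_green, cfg$sign$ref_blue)
  sc_sign <- generate_scene(scene_params(pose = "sign", seed = 77,
                                         defects = "lighting_shift",
                                         lighting_gain = 0.8), test_config())
  tf <- estimate_color_transform(detect_sign(sc_sign$image, test_config()), refs)
  eye <- generate_eye_scene(2, seed = 6, noise_sd = 0, config = cfg)
  dimmed <- pmax(pmin(round(eye$image$pixels * 0.8), 255), 0)
  fr_ref <- famacha_score(eye$image, identity_transform(), cfg$famacha$refs, cfg)
  fr_dim <- famacha_score(dimmed, tf, cfg$famacha$refs, cfg)
  expect_equal(fr_dim$category, fr_ref$category)
})

test_that("tooth age counts permanent pairs and clamps at four", {
  cfg <- full_config()
  for (p in c(0L, 2L, 4L)) {
    sc <- generate_teeth_scene(p, seed = p + 3, config = cfg)
    ta <- tooth_age(sc$image, config = cfg)
    expect_equal(ta$permanent_pairs, p)
  }
  expect_equal(tooth_age(generate_teeth_scene(0, seed = 1)$image)$age_class, "<1 yr")
  # nine qualifying regions still clamp to 4 pairs
  img <- array(40, c(320, 420, 3))
  for (i in 0:8) img[100:160, (i * 45 + 10):(i * 45 + 40), ] <- 230
  ta9 <- tooth_age(img, config = cfg)
  expect_equal(ta9$permanent_pairs, 4L)
  # no tooth-like regions at all
  expect_error(tooth_age(array(30, c(100, 100, 3))), "teeth")
})
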