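# synthetic scene generator: determinism, geometry, defects, close-ups

test_that("scene generation is deterministic and geometrically exact", {
  cfg <- test_config()
  a <- generate_scene(scene_params(pose = "sign", seed = 7), cfg)
  b <- generate_scene(scene_params(pose = "sign", seed = 7), cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$mask, b$truth$mask)
  # withers sits HW * ppcm pixels above the ground row
  ppcm <- cfg$frame$pixels_per_cm
  expect_equal(a$truth$ground_row - a$truth$withers["row"],
               round(60 * ppcm), ignore_attr = TRUE)
  # the mask is exactly the rendered goat pixels: goat colors only
  coat <- c(196, 160, 110)
  on_goat <- a$image$pixels[, , 1][a$truth$mask]
  expect_true(all(on_goat == coat[1]))
  # true scale is the sign's physical width over its rendered pixel width
  co <- a$truth$sign_corners
  expect_equal(cfg$sign$width_cm / (co["TR", "col"] - co["TL", "col"] + 1),
               a$truth$scale)
})

test_that("scene parameters are validated", {
  expect_error(scene_params(chest_depth = 70, hw = 60), "chest_depth")
  expect_error(scene_params(camera = list(distance_m = 2)), "3 m")
  expect_error(scene_params(defects = "mud_monster"), "defects")
  expect_error(scene_params(hw = -2), "")
  # goat larger than the frame at this scale
  expect_error(generate_scene(scene_params(hw = 200, bl = 300, chest_depth = 80,
                                           chest_width = 40), test_config()),
               "fit")
})

test_that("defect-free backgrounds are overwhelmingly blue; dirty tarp lowers it", {
  cfg <- test_config()
  clean <- std_scene("sign", seed = 55)
  bg <- classify_blue(clean$image, cfg$blue)
  expect_gte(mean(bg[!clean$truth$mask]), 0.95)
  dirty <- generate_scene(scene_params(pose = "sign", seed = 55,
                                       defects = "dirty_tarp"), cfg)
  bg_d <- classify_blue(dirty$image, cfg$blue)
  expect_lt(mean(bg_d[!dirty$truth$mask]), mean(bg[!clean$truth$mask]))
})

test_that("side pose has no sign; sign/rear poses have one in the subject plane", {
  expect_null(std_scene("side", seed = 9)$truth$sign_corners)
  for (pose in c("sign", "rear")) {
    sc <- std_scene(pose, seed = 9)
    expect_false(is.null(sc$truth$sign_corners))
  }
})

test_that("eye scenes render the requested category color with bounded noise", {
  cfg <- full_config()
  refs <- cfg$famacha$refs
  # zero noise: conjunctiva pixels exactly equal the reference
  sc <- generate_eye_scene(1, seed = 3, noise_sd = 0, config = cfg)
  px <- sapply(1:3, function(ch) unique(sc$image$pixels[, , ch][sc$truth$conj_mask]))
  expect_equal(as.numeric(px), as.numeric(refs[1, ]))
  # labels pass through
  cats <- vapply(1:5, function(k) {
    generate_eye_scene(k, seed = k, config = cfg)$truth$category
  }, 0)
  expect_equal(cats, 1:5)
  # noise sd 4: ROI mean within 2 units of the reference per channel
  sc4 <- generate_eye_scene(3, seed = 11, noise_sd = 4, config = cfg)
  expect_gte(sum(sc4$truth$conj_mask), 1000)
  mu <- sapply(1:3, function(ch) mean(sc4$image$pixels[, , ch][sc4$truth$conj_mask]))
  expect_true(all(abs(mu - refs[3, ]) < 2))
  expect_error(generate_eye_scene(0), "1..5")
  expect_error(generate_eye_scene(6), "1..5")
})

test_that("teeth scenes scale permanent-tooth area with the pair count", {
  areas <- vapply(0:4, function(p) {
    generate_teeth_scene(p, seed = p + 1)$truth$permanent_area_px
  }, 0)
  expect_equal(areas[1], 0)
  expect_true(all(diff(areas) > 0))
  sc4 <- generate_teeth_scene(4, seed = 2)
  expect_equal(sum(vapply(sc4$truth$teeth, function(t) t$permanent, TRUE)), 8L)
  sc0 <- generate_teeth_scene(0, seed = 2)
  expect_true(all(vapply(sc0$truth$teeth, function(t) t$area, 0) < 600))
  expect_error(generate_teeth_scene(5), "0..4")
})

test_that("synth_batch writes images, masks and ground truth", {
  td <- tempfile()
  truth <- synth_batch(2, seed = 4, pose_set = "measures-only", out_dir = td,
                       config = test_config())
  expect_equal(nrow(truth), 2L)
  expect_true(file.exists(file.path(td, "ground_truth.csv")))
  expect_length(list.files(td, pattern = "_sign\\.png$"), 2L)
  expect_length(list.files(file.path(td, "masks")), 4L)
  mf <- read_manifest(file.path(td, "manifest.csv"))
  expect_equal(nrow(mf), 4L)
})
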