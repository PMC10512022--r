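# chroma-key classification, prior-based isolation, edge refinement, QC

test_that("classify_blue marks pure blue background and leaves red alone", {
  blue <- array(0, c(20, 30, 3)); blue[, , 3] <- 200; blue[, , 1] <- 40; blue[, , 2] <- 80
  expect_true(all(classify_blue(blue)))
  red <- array(0, c(20, 30, 3)); red[, , 1] <- 200
  expect_false(any(classify_blue(red)))
})

test_that("background classification matches scene truth to 99 percent", {
  cfg <- test_config()
  sc <- std_scene("sign", seed = 42)
  bg <- classify_blue(sc$image, cfg$blue)
  co <- sc$truth$sign_corners
  sign_region <- matrix(FALSE, nrow(bg), ncol(bg))
  sign_region[co["TL", "row"]:co["BL", "row"], co["TL", "col"]:co["TR", "col"]] <- TRUE
  foreground_truth <- sc$truth$mask | sign_region
  expect_gte(mean(bg == !foreground_truth), 0.99)
})

test_that("isolation priors exclude small and off-center blobs, fill holes, break ties", {
  img <- array(0, c(200, 200, 3)); img[, , 3] <- 200; img[, , 2] <- 80; img[, , 1] <- 40
  bg <- classify_blue(img)
  draw <- function(bgr, r, cc, h, w) { bgr[r:(r + h - 1), cc:(cc + w - 1)] <- FALSE; bgr }
  # centered goat-sized blob with a hole + a tiny rock
  bg1 <- draw(bg, 80, 80, 50, 60)
  bg1[100:105, 100:105] <- TRUE            # interior hole
  bg1 <- draw(bg1, 190, 10, 5, 8)          # rock, below min area
  mk <- isolate_roi(img, bg1, list(min_area_frac = 0.02, max_area_frac = 0.4,
                                   max_centroid_offset_frac = 0.25))
  expect_equal(mk$component_area, 50 * 60)  # hole filled, rock excluded
  expect_false(mk$mask[195, 12])
  # equal-area tie: the centered blob wins
  bg2 <- draw(bg, 85, 85, 30, 30)
  bg2 <- draw(bg2, 10, 150, 30, 30)        # same area, off center but within priors
  mk2 <- isolate_roi(img, bg2, list(min_area_frac = 0.01, max_area_frac = 0.4,
                                    max_centroid_offset_frac = 0.6))
  expect_true(mk2$mask[90, 90])
  expect_false(mk2$mask[15, 155])
  # nothing qualifying: error carries the candidate list
  err <- tryCatch(isolate_roi(img, draw(bg, 1, 1, 4, 4),
                              list(min_area_frac = 0.02, max_area_frac = 0.4,
                                   max_centroid_offset_frac = 0.25)),
                  goatpheno_no_subject = function(e) e)
  expect_s3_class(err, "goatpheno_no_subject")
  expect_true(is.data.frame(err$candidates))
})

test_that("subject isolation is invariant to a 20 percent brightness change", {
  cfg <- test_config()
  sc <- std_scene("side", seed = 13)
  ref <- isolate_roi(sc$image, classify_blue(sc$image, cfg$blue), cfg$priors)
  for (g in c(0.8, 1.2)) {
    img2 <- pmin(pmax(round(sc$image$pixels * g), 0), 255)
    mk2 <- isolate_roi(img2, classify_blue(img2, cfg$blue), cfg$priors)
    expect_identical(mk2$mask, ref$mask)
  }
})

test_that("edge refinement recovers the true silhouette from perturbed masks", {
  cfg <- test_config()
  sc <- std_scene("side", seed = 31)
  truth <- sc$truth$mask
  # step edge: a 3 px dilated mask snaps back exactly
  dil <- goatpheno:::dilate_mask(truth, 3)
  expect_identical(refine_edges(sc$image, dil)$mask, truth)
  # and a 3 px eroded mask grows back exactly
  ero <- goatpheno:::erode_mask(truth, 3)
  expect_identical(refine_edges(sc$image, ero)$mask, truth)
})

test_that("refinement on a blurred edge stays within a pixel and is idempotent", {
  cfg <- test_config()
  sc <- std_scene("side", seed = 31)
  imgb <- blur_image(sc$image$pixels, 2)
  mk <- isolate_roi(imgb, classify_blue(imgb, cfg$blue), cfg$priors)
  r1 <- refine_edges(imgb, mk)
  bt <- goatpheno:::mask_boundary(sc$truth$mask)
  br <- goatpheno:::mask_boundary(r1$mask)
  dist_to_truth <- goatpheno:::mask_distmap(!bt)
  expect_lte(mean(dist_to_truth[br]), 1)
  r2 <- refine_edges(imgb, r1)
  expect_lte(sum(r2$mask != r1$mask), 0.001 * sum(goatpheno:::mask_boundary(r1$mask)))
})

test_that("QC flags clean scenes as clean and each staged defect by its code", {
  cfg <- test_config()
  sc <- std_scene("sign", seed = 42)
  mk <- segment_scene(sc, cfg, refine = FALSE)
  det <- detect_sign(sc$image, cfg)
  expect_length(qc_scene(sc$image, mk, cfg, sign_mask = det$sign_mask), 0L)
  # rocks hide the feet
  rocks <- generate_scene(scene_params(pose = "side", seed = 6, defects = "rocks"), cfg)
  mk_r <- isolate_roi(rocks$image, classify_blue(rocks$image, cfg$blue), cfg$priors)
  expect_true("FEET_NOT_ON_GROUND_LINE" %in% qc_scene(rocks$image, mk_r, cfg))
  # dirty tarp kills the blue coverage
  dirty <- generate_scene(scene_params(pose = "side", seed = 6, defects = "dirty_tarp"), cfg)
  mk_d <- isolate_roi(dirty$image, classify_blue(dirty$image, cfg$blue), cfg$priors)
  expect_true("LOW_BLUE_COVERAGE" %in% qc_scene(dirty$image, mk_d, cfg))
  # a handler limb close to the subject
  occ <- generate_scene(scene_params(pose = "side", seed = 6,
                                     defects = "handler_occluder"), cfg)
  mk_o <- isolate_roi(occ$image, classify_blue(occ$image, cfg$blue), cfg$priors)
  expect_true("NON_BLUE_OBJECT_NEAR_SUBJECT" %in% qc_scene(occ$image, mk_o, cfg))
})
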