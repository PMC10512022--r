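# Shared fixtures: scenes are expensive to render, so commonly reused ones
# are memoized for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# smaller frame for unit tests; geometry and priors scale with it
test_config <- function() {
  goat_config(list(frame = list(size = c(400L, 500L), pixels_per_cm = 2.5)))
}

full_config <- function() goat_config()

# canonical clean scenes on the small frame
std_scene <- function(pose = "sign", seed = 42, ...) {
  key <- paste0("scene_", pose, "_", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  cached(key, generate_scene(scene_params(pose = pose, seed = seed, ...),
                             test_config()))
}

# the acceptance cohort (full frame, n = 200) shared between files
cached_cohort <- function() {
  cached("cohort200", run_recovery_cohort(n = 200, seed = 1, config = goat_config()))
}

# segment a scene end to end with the matching priors
segment_scene <- function(sc, cfg, refine = TRUE) {
  bg <- classify_blue(sc$image, cfg$blue)
  pose <- sc$image$pose
  pri <- cfg$priors
  if (pose == "rear") pri$min_area_frac <- pri$rear_min_area_frac
  excl <- if (pose %in% c("sign", "rear")) {
    tryCatch(detect_sign(sc$image, cfg)$sign_mask, error = function(e) NULL)
  }
  mk <- isolate_roi(sc$image, bg, pri, exclude = excl)
  if (refine) mk <- refine_edges(sc$image, mk, cfg$refine$window_px, cfg$refine$min_grad)
  mk
}

blur_image <- function(img, sigma = 2) {
  for (ch in 1:3) {
    img[, , ch] <- t(EBImage::imageData(EBImage::gblur(t(img[, , ch]), sigma = sigma)))
  }
  pmin(pmax(img, 0), 255)
}
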