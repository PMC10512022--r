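# Synthetic-cohort evaluation: ground-truth recovery over seeded scene
# populations. These drive the validation suites and the acceptance
# summary; sample sizes are arguments so small smoke runs and full cohorts
# share one code path.

draw_cohort_params <- function(n, seed) {
  with_seed(seed, {
    data.frame(
      hw = runif(n, 40, 90),
      bl = runif(n, 50, 100),
      depth = runif(n, 20, 40),
      width = runif(n, 12, 30),
      coat = sample(c("tan", "brown", "black", "white"), n, replace = TRUE),
      scene_seed = sample.int(2^30, n)
    )
  })
}

#' Ground-truth recovery over a synthetic cohort
#'
#' Generates `n` defect-free synthetic animals with dimensions drawn
#' uniformly (HW 40-90 cm, BL 50-100 cm, chest depth 20-40 cm, chest width
#' 12-30 cm), renders the sign and rear poses, runs the full measurement
#' pipeline (chroma-key segmentation, boundary refinement, sign
#' calibration, morphometry) and returns recovered vs true measures.
#'
#' @param n cohort size.
#' @param seed integer seed driving all draws.
#' @param config a [goat_config()].
#' @param refine run boundary refinement (the full pipeline) when `TRUE`.
#' @return data.frame with true/recovered HW, BL, depth, width, CG and an
#'   `ok` indicator per scene; failed scenes carry `NA` recoveries.
#' @export
run_recovery_cohort <- function(n = 200, seed = 1L, config = goat_config(),
                                refine = TRUE) {
  pars <- draw_cohort_params(n, seed)
  cfg <- config
  res <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pars[i, ]
    coat <- cfg$scene$coat_palette[[p$coat]]
    rec <- tryCatch({
      sp_sign <- scene_params(hw = p$hw, bl = p$bl, chest_depth = p$depth,
                              chest_width = p$width, pose = "sign",
                              coat_colors = list(coat), seed = p$scene_seed)
      sc <- generate_scene(sp_sign, cfg)
      sp_rear <- scene_params(hw = p$hw, bl = p$bl, chest_depth = p$depth,
                              chest_width = p$width, pose = "rear",
                              coat_colors = list(coat), seed = p$scene_seed + 1L)
      rr <- generate_scene(sp_rear, cfg)

      cal <- calibrate_from_sign(sc$image, cfg)
      bg <- classify_blue(sc$image, cfg$blue)
      mk <- isolate_roi(sc$image, bg, cfg$priors, exclude = cal$detection$sign_mask)
      if (refine) mk <- refine_edges(sc$image, mk, cfg$refine$window_px,
                                     cfg$refine$min_grad)
      g <- ground_row(mk)
      hw <- height_at_withers(mk, cal$scale, g, cfg$bands)$HW
      bl <- body_length(mk, cal$scale, g, cfg$bands)$BL
      dp <- chest_depth(mk, cal$scale, g, cfg$bands)

      cal_r <- calibrate_from_sign(rr$image, cfg)
      bg_r <- classify_blue(rr$image, cfg$blue)
      pri <- cfg$priors
      pri$min_area_frac <- pri$rear_min_area_frac
      mk_r <- isolate_roi(rr$image, bg_r, pri, exclude = cal_r$detection$sign_mask)
      if (refine) mk_r <- refine_edges(rr$image, mk_r, cfg$refine$window_px,
                                       cfg$refine$min_grad)
      cw <- chest_width(mk_r, cal_r$scale, cfg$bands)

      data.frame(hw_true = p$hw, bl_true = p$bl, depth_true = p$depth,
                 width_true = p$width,
                 cg_true = chest_girth(p$depth, p$width),
                 hw_rec = hw, bl_rec = bl, depth_rec = dp, width_rec = cw,
                 cg_rec = chest_girth(dp, cw),
                 scale_rec = cal$scale, scale_true = sc$truth$scale,
                 ok = TRUE)
    }, error = function(e) {
      data.frame(hw_true = p$hw, bl_true = p$bl, depth_true = p$depth,
                 width_true = p$width, cg_true = chest_girth(p$depth, p$width),
                 hw_rec = NA_real_, bl_rec = NA_real_, depth_rec = NA_real_,
                 width_rec = NA_real_, cg_rec = NA_real_,
                 scale_rec = NA_real_, scale_true = NA_real_, ok = FALSE)
    })
    res[[i]] <- rec
  }
  do.call(rbind, res)
}

#' Cohort correlation summary
#'
#' Pearson correlations between recovered and ground-truth measures over a
#' recovery cohort, on complete cases.
#'
#' @param cohort data.frame from [run_recovery_cohort()].
#' @return named numeric vector `r_hw`, `r_bl`, `r_cg`, plus `n_ok`.
#' @export
cohort_correlations <- function(cohort) {
  r <- function(a, b) {
    ok <- stats::complete.cases(a, b)
    stats::cor(a[ok], b[ok])
  }
  c(r_hw = r(cohort$hw_rec, cohort$hw_true),
    r_bl = r(cohort$bl_rec, cohort$bl_true),
    r_cg = r(cohort$cg_rec, cohort$cg_true),
    n_ok = sum(cohort$ok))
}

#' Mask pixel accuracy over defect-free scenes
#'
#' Renders `n` seeded side-view scenes, runs segmentation plus refinement,
#' and reports per-scene pixel agreement with the ground-truth mask.
#'
#' @inheritParams run_recovery_cohort
#' @return numeric vector of pixel accuracies in `[0, 1]`.
#' @export
mask_accuracy_cohort <- function(n = 100, seed = 1L, config = goat_config()) {
  pars <- draw_cohort_params(n, seed)
  cfg <- config
  vapply(seq_len(n), function(i) {
    p <- pars[i, ]
    coat <- cfg$scene$coat_palette[[p$coat]]
    sp <- scene_params(hw = p$hw, bl = p$bl, chest_depth = p$depth,
                       chest_width = p$width, pose = "side",
                       coat_colors = list(coat), seed = p$scene_seed)
    sc <- generate_scene(sp, cfg)
    bg <- classify_blue(sc$image, cfg$blue)
    mk <- isolate_roi(sc$image, bg, cfg$priors)
    mk <- refine_edges(sc$image, mk, cfg$refine$window_px, cfg$refine$min_grad)
    mean(mk$mask == sc$truth$mask)
  }, 0)
}

#' Calibration recovery under lighting shifts
#'
#' Renders `n` sign-pose scenes with lighting gains drawn uniformly from
#' `gain_range`, and reports the recovered scale and the gain implied by
#' the fitted color transform (reciprocal of the mean diagonal).
#'
#' @inheritParams run_recovery_cohort
#' @param gain_range range of channel gains.
#' @return data.frame: `gain_true`, `gain_rec`, `scale_rec`, `scale_true`,
#'   `block_err` (mean abs corrected-block error).
#' @export
calibration_recovery_cohort <- function(n = 50, seed = 1L,
                                        gain_range = c(0.7, 1.3),
                                        config = goat_config()) {
  pars <- draw_cohort_params(n, seed)
  gains <- with_seed(seed + 1L, runif(n, gain_range[1], gain_range[2]))
  cfg <- config
  refs <- rbind(cfg$sign$ref_border, cfg$sign$ref_red,
                cfg$sign$ref_green, cfg$sign$ref_blue)
  res <- lapply(seq_len(n), function(i) {
    p <- pars[i, ]
    coat <- cfg$scene$coat_palette[[p$coat]]
    sp <- scene_params(hw = p$hw, bl = p$bl, chest_depth = p$depth,
                       chest_width = p$width, pose = "sign",
                       coat_colors = list(coat), seed = p$scene_seed,
                       defects = "lighting_shift", lighting_gain = gains[i])
    sc <- generate_scene(sp, cfg)
    det <- detect_sign(sc$image, cfg)
    tf <- estimate_color_transform(det, refs)
    corrected <- apply_color_transform(det$block_colors, tf)
    block_err <- mean(abs(corrected - refs[2:4, ]))
    data.frame(gain_true = gains[i], gain_rec = 1 / mean(diag(tf$M)),
               scale_rec = spatial_scale(det, c(cfg$sign$width_cm, cfg$sign$height_cm)),
               scale_true = sc$truth$scale, block_err = block_err)
  })
  do.call(rbind, res)
}

#' FAMACHA classification accuracy by simulation
#'
#' Generates `n_per_cat` synthetic eyes per category with the configured
#' noise and scores them; returns the confusion summary.
#'
#' @param n_per_cat eyes per category.
#' @param seed integer seed.
#' @param noise_sd channel noise sd.
#' @param config a [goat_config()].
#' @return list `accuracy`, `n`, `confusion` (5 x 5 table).
#' @export
famacha_simulation <- function(n_per_cat = 50, seed = 1L, noise_sd = 4,
                               config = goat_config()) {
  cfg <- config
  truth <- integer(); pred <- integer()
  k <- 0L
  for (cat in 1:5) {
    for (j in seq_len(n_per_cat)) {
      k <- k + 1L
      sc <- generate_eye_scene(cat, seed = seed * 13L + k, noise_sd = noise_sd,
                               config = cfg)
      fr <- famacha_score(sc$image, identity_transform(), cfg$famacha$refs, cfg)
      truth <- c(truth, cat); pred <- c(pred, fr$category)
    }
  }
  list(accuracy = mean(truth == pred), n = length(truth),
       confusion = table(truth = truth, pred = pred))
}

#' QC defect-detection rates
#'
#' Renders `n` scenes per defect class and reports how often the
#' designated flag is raised: `dirty_tarp` -> `LOW_BLUE_COVERAGE`,
#' `rocks` -> `FEET_NOT_ON_GROUND_LINE`, `missing_ground_tarp` ->
#' `SUBJECT_TOUCHES_BORDER` (the subject merges with the non-blue ground
#' and reaches the frame border).
#'
#' @param n scenes per defect class.
#' @param seed integer seed.
#' @param config a [goat_config()].
#' @return named numeric vector of detection rates in `[0, 1]`.
#' @export
qc_detection_rates <- function(n = 30, seed = 1L, config = goat_config()) {
  cfg <- config
  pars <- draw_cohort_params(n, seed)
  cases <- list(dirty_tarp = "LOW_BLUE_COVERAGE",
                rocks = "FEET_NOT_ON_GROUND_LINE",
                missing_ground_tarp = "SUBJECT_TOUCHES_BORDER")
  out <- vapply(names(cases), function(defect) {
    hits <- vapply(seq_len(n), function(i) {
      p <- pars[i, ]
      coat <- cfg$scene$coat_palette[[p$coat]]
      sp <- scene_params(hw = p$hw, bl = p$bl, chest_depth = p$depth,
                         chest_width = p$width, pose = "side",
                         coat_colors = list(coat), seed = p$scene_seed + 7L,
                         defects = defect)
      sc <- generate_scene(sp, cfg)
      bg <- classify_blue(sc$image, cfg$blue)
      mk <- tryCatch(isolate_roi(sc$image, bg, cfg$priors),
                     error = function(e) NULL)
      if (is.null(mk)) {
        # priors rejected everything (e.g. subject fused with a non-blue
        # ground): QC falls back to the largest foreground component
        lab <- label_components(!bg)
        st <- component_stats(lab)
        mk <- new_goat_mask(lab == st$label[which.max(st$area)])
      }
      cases[[defect]] %in% qc_scene(sc$image, mk, cfg)
    }, TRUE)
    mean(hits)
  }, 0)
  names(out) <- names(cases)
  out
}
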