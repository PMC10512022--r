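# Batch synthetic-scene writer backing the `synth` CLI subcommand.

#' Write a batch of synthetic animals to disk
#'
#' Generates `n` synthetic animals (dimensions drawn as in
#' [run_recovery_cohort()]), writes the pose images as PNG, per-scene
#' ground-truth masks as PNG, and a ground-truth annotation table as csv.
#'
#' @param n number of animals.
#' @param seed integer seed.
#' @param pose_set `"full"` (sign, rear, side, eye, teeth) or
#'   `"measures-only"` (sign, rear).
#' @param defects character vector of defects injected into every scene.
#' @param out_dir output directory.
#' @param config a [goat_config()].
#' @return invisible data.frame: the ground-truth table that was written.
#' @export
synth_batch <- function(n, seed = 1L, pose_set = c("full", "measures-only"),
                        defects = character(), out_dir, config = goat_config()) {
  pose_set <- match.arg(pose_set)
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  pars <- draw_cohort_params(n, seed)
  rows <- list()
  manifest <- list()
  for (i in seq_len(n)) {
    p <- pars[i, ]
    id <- sprintf("SYN%04d", i)
    coat <- cfg$scene$coat_palette[[p$coat]]
    poses <- c("sign", "rear")
    if (pose_set == "full") poses <- c(poses, "side")
    for (pose in poses) {
      sp <- scene_params(hw = p$hw, bl = p$bl, chest_depth = p$depth,
                         chest_width = p$width, pose = pose,
                         coat_colors = list(coat), defects = defects,
                         seed = p$scene_seed + match(pose, c("sign", "rear", "side")))
      sc <- generate_scene(sp, cfg)
      img_file <- file.path(out_dir, sprintf("%s_%s.png", id, pose))
      png::writePNG(sc$image$pixels / 255, img_file)
      png::writePNG(sc$truth$mask * 1, file.path(out_dir, "masks",
                                                 sprintf("%s_%s_mask.png", id, pose)))
      manifest[[length(manifest) + 1L]] <-
        data.frame(sample_id = id, pose = pose, path = img_file)
    }
    fam_cat <- eye_pairs <- NA_integer_
    if (pose_set == "full") {
      fam_cat <- with_seed(p$scene_seed + 11L, sample(1:5, 1))
      eye <- generate_eye_scene(fam_cat, seed = p$scene_seed + 12L, config = cfg)
      eye_file <- file.path(out_dir, sprintf("%s_eye.png", id))
      png::writePNG(eye$image$pixels / 255, eye_file)
      eye_pairs <- with_seed(p$scene_seed + 13L, sample(0:4, 1))
      th <- generate_teeth_scene(eye_pairs, seed = p$scene_seed + 14L, config = cfg)
      teeth_file <- file.path(out_dir, sprintf("%s_teeth.png", id))
      png::writePNG(th$image$pixels / 255, teeth_file)
      manifest[[length(manifest) + 1L]] <-
        data.frame(sample_id = id, pose = "eye", path = eye_file)
      manifest[[length(manifest) + 1L]] <-
        data.frame(sample_id = id, pose = "teeth", path = teeth_file)
    }
    rows[[i]] <- data.frame(
      sample_id = id, HW = p$hw, BL = p$bl, chest_depth = p$depth,
      chest_width = p$width, CG = chest_girth(p$depth, p$width),
      famacha = fam_cat, permanent_pairs = eye_pairs,
      defects = paste(defects, collapse = ";"))
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, manifest), file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(truth)
}
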