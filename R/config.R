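#' Default pipeline configuration
#'
#' Returns the full configuration list used by every stage of the pipeline
#' and by the synthetic-scene generator. All thresholds that the protocol
#' leaves unspecified (blue hue band, size/centering priors, measurement
#' bands, reference colors) live here so that the generator and the
#' extraction stages share a single source of truth.
#'
#' Key groups:
#' \describe{
#'   \item{frame}{default render size `c(rows, cols)` and pixels per cm at
#'     the subject plane (camera at >= 3 m, eye level, sign in plane).}
#'   \item{sign}{physical outer dimensions (cm), border thickness, and the
#'     reference colors of the black border and the pure R/G/B blocks.}
#'   \item{blue}{HSV chroma-key band: hue in degrees, minimum saturation and
#'     value. Hue-based classification is robust to brightness shifts.}
#'   \item{priors}{subject-isolation priors: component area as a fraction of
#'     the frame and maximum centroid offset as a fraction of the diagonal.}
#'   \item{bands}{fractional silhouette bands locating withers, the
#'     shoulder/pin length band, the chest-depth column band and the rear
#'     barrel band. Fractions of mask extent, not absolute pixels.}
#'   \item{famacha}{the five conjunctiva reference colors ordered from
#'     category 1 (healthy deep red) to 5 (anemic pale pink), and the ROI
#'     color-distance gate.}
#'   \item{teeth}{brightness/chroma gate for tooth pixels and the area rules
#'     separating permanent from deciduous incisors.}
#'   \item{qc}{flag thresholds: minimum blue coverage, expected ground-row
#'     band, proximity distance for foreign objects.}
#' }
#'
#' @param overrides optional named list (possibly nested) merged over the
#'   defaults; unknown keys are rejected.
#' @return a nested list of class `goat_config`.
#' @export
#' @examples
#' cfg <- goat_config()
#' cfg$sign$width_cm
#' cfg2 <- goat_config(list(sign = list(width_cm = 50)))
goat_config <- function(overrides = NULL) {
  cfg <- list(
    frame = list(
      size = c(800L, 1000L),       # rows, cols
      pixels_per_cm = 5,
      eye_size = c(320L, 420L),
      teeth_size = c(320L, 420L)
    ),
    scene = list(
      backdrop_rgb = c(50, 95, 205),
      tarp_rgb = c(38, 80, 188),
      ground_row_frac = 0.88,      # where feet meet the tarp
      tarp_top_frac = 0.62,        # backdrop/ground-cloth fold line
      coat_palette = list(
        tan = c(196, 160, 110), brown = c(120, 80, 48),
        black = c(45, 38, 34), white = c(235, 230, 222)
      ),
      skin_rgb = c(205, 170, 150),
      rock_rgb = c(110, 105, 100),
      dirt_rgb = c(105, 85, 60)
    ),
    sign = list(
      width_cm = 40, height_cm = 30, border_cm = 3,
      # measured colors of the printed card: ink-level "pure" blocks rather
      # than digital 255, so exposure shifts up to +30% stay on-range
      ref_border = c(0, 0, 0),
      ref_red = c(190, 0, 0), ref_green = c(0, 190, 0), ref_blue = c(0, 0, 190),
      interior_rgb = c(245, 245, 245),
      min_border_score = 0.7, low_conf_border_score = 0.5,
      dark_value_max = 0.25      # HSV value below which a pixel counts as border-dark
    ),
    blue = list(hue = c(190, 250), s_min = 0.25, v_min = 0.15),
    priors = list(min_area_frac = 0.02, max_area_frac = 0.40,
                  max_centroid_offset_frac = 0.25,
                  rear_min_area_frac = 0.008),  # rear view subtends less area
    refine = list(window_px = 5L, min_grad = 8),
    bands = list(
      withers_front = c(0.20, 0.45),   # of body span, from the front
      length_height = c(0.45, 0.75),   # of body height, from the ground
      depth_back = 0.55,               # column band depth behind the forelegs
      rear_barrel = c(0.20, 0.70)      # of mask height, from the top
    ),
    famacha = list(
      refs = rbind(c(165, 35, 45), c(190, 80, 90), c(210, 125, 135),
                   c(230, 170, 180), c(245, 215, 220)),
      roi_max_dist = 60,       # RGB distance gate for conjunctiva pixels
      noise_sd = 4
    ),
    teeth = list(
      min_bright = 180, max_chroma = 40,
      ratio_thresh = 0.5, abs_min_frac = 0.008,
      age_map = c("<1 yr", "1-2 yr", "2-3 yr", "3-4 yr", ">=4 yr")
    ),
    coat = list(K = 3L, merge_frac = 0.05, solid_frac = 0.90,
                downsample = 8L, min_area_px = 1000L, seed = 71L),
    weight = list(formula = "cg2bl", k = 10838),
    qc = list(
      min_blue_coverage = 0.80,
      ground_row_frac = 0.88, ground_tol_frac = 0.05,
      near_dist_px = 30L, near_min_px = 400L
    )
  )
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides, "config")
  class(cfg) <- "goat_config"
  cfg
}

merge_config <- function(base, over, path) {
  stopifnot(is.list(over))
  for (nm in names(over)) {
    if (!nm %in% names(base)) {
      stop("unknown config key: ", path, "$", nm, call. = FALSE)
    }
    if (is.list(base[[nm]]) && is.list(over[[nm]]) && !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], paste0(path, "$", nm))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Load a configuration file
#'
#' Reads a YAML file of overrides and merges it over [goat_config()]
#' defaults.
#'
#' @param path YAML file; top-level keys must match config groups.
#' @return a `goat_config` list.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  goat_config(yaml::read_yaml(path))
}

#' @export
print.goat_config <- function(x, ...) {
  cat("goat phenotyping configuration\n")
  cat("  frame:", paste(x$frame$size, collapse = " x "),
      sprintf("px at %.3g px/cm\n", x$frame$pixels_per_cm))
  cat("  sign :", x$sign$width_cm, "x", x$sign$height_cm, "cm,",
      x$sign$border_cm, "cm border\n")
  cat("  blue : hue", paste(x$blue$hue, collapse = "-"),
      "deg, S >=", x$blue$s_min, ", V >=", x$blue$v_min, "\n")
  invisible(x)
}
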