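# health_phenotypes: FAMACHA conjunctiva anemia category from the eye
# close-up and tooth-eruption age class from the teeth close-up.

#' FAMACHA anemia score from an eye close-up
#'
#' Locates the conjunctiva as the largest connected region whose
#' color-corrected pixels fall in the red-pink range (within the configured
#' distance of any of the five reference colors), then assigns the category
#' of the nearest reference in CIELAB perceptual distance. Distance ties
#' break toward the higher (more anemic) category — clinically
#' conservative.
#'
#' @param image `goat_image` (eye pose) or array.
#' @param transform a `color_transform` (identity if no calibration).
#' @param reference 5 x 3 matrix of category reference RGB rows, 1 = healthy
#'   deep red through 5 = anemic pale; default from [goat_config()].
#' @param config a [goat_config()].
#' @return object of class `famacha_result`: `category` (1-5),
#'   `measured_color` (corrected mean RGB), `distances` (per category),
#'   `confidence` (margin between best and second best), `roi_px`.
#' @export
famacha_score <- function(image, transform = identity_transform(),
                          reference = NULL, config = goat_config()) {
  img <- if (inherits(image, "goat_image")) image$pixels else image
  assert_image(img)
  cfg <- config
  refs <- reference %||% cfg$famacha$refs
  stopifnot(nrow(refs) == 5L)
  corrected <- apply_color_transform(img, transform)
  d <- dim(corrected)
  px <- cbind(as.vector(corrected[, , 1]), as.vector(corrected[, , 2]),
              as.vector(corrected[, , 3]))
  # red-pink gate: close to any reference in RGB
  mind <- rep(Inf, nrow(px))
  for (k in 1:5) {
    dk <- sqrt((px[, 1] - refs[k, 1])^2 + (px[, 2] - refs[k, 2])^2 +
                 (px[, 3] - refs[k, 3])^2)
    mind <- pmin(mind, dk)
  }
  gate <- matrix(mind <= cfg$famacha$roi_max_dist, d[1], d[2])
  lab <- label_components(gate)
  st <- component_stats(lab)
  if (nrow(st) == 0L) stop("conjunctiva not found", call. = FALSE)
  roi <- lab == st$label[which.max(st$area)]
  mcol <- c(mean(corrected[, , 1][roi]), mean(corrected[, , 2][roi]),
            mean(corrected[, , 3][roi]))
  lab_refs <- rgb_to_lab(refs)
  lab_m <- rgb_to_lab(matrix(mcol, 1))
  dists <- sqrt(rowSums((lab_refs - matrix(lab_m, 5, 3, byrow = TRUE))^2))
  best <- max(which(dists <= min(dists) + 1e-9))   # tie -> more anemic
  s <- sort(dists)
  structure(list(category = best, measured_color = mcol, distances = dists,
                 confidence = s[2] - s[1], roi_px = sum(roi)),
            class = "famacha_result")
}

#' @export
print.famacha_result <- function(x, ...) {
  cat(sprintf("FAMACHA category %d (margin %.1f dE, ROI %d px)\n",
              x$category, x$confidence, x$roi_px))
  invisible(x)
}

#' Tooth-eruption age class from a teeth close-up
#'
#' Segments tooth-colored regions (bright, low chroma), splits them into
#' permanent vs deciduous incisors by area — a region is permanent when its
#' area reaches both the configured fraction of the largest tooth and an
#' absolute minimum (the protocol's fixed close-up framing keeps scale
#' roughly constant) — and maps half the permanent count (pairs, clamped to
#' 0..4) through the configured age classes.
#'
#' @param image `goat_image` (teeth pose) or array.
#' @param mapping character vector of 5 labels for 0..4 permanent pairs.
#' @param config a [goat_config()].
#' @return object of class `tooth_age`: `permanent_pairs`, `age_class`,
#'   `n_regions`, `areas`.
#' @export
tooth_age <- function(image, mapping = goat_config()$teeth$age_map,
                      config = goat_config()) {
  img <- if (inherits(image, "goat_image")) image$pixels else image
  assert_image(img)
  stopifnot(length(mapping) == 5L)
  tc <- config$teeth
  lo <- pmin(img[, , 1], pmin(img[, , 2], img[, , 3]))
  hi <- pmax(img[, , 1], pmax(img[, , 2], img[, , 3]))
  toothy <- lo >= tc$min_bright & (hi - lo) <= tc$max_chroma
  lab <- label_components(toothy)
  st <- component_stats(lab)
  st <- st[st$area >= 20, , drop = FALSE]   # specks are noise
  if (nrow(st) == 0L) stop("teeth not found", call. = FALSE)
  amax <- max(st$area)
  abs_min <- tc$abs_min_frac * prod(dim(img)[1:2])
  perm <- st$area >= tc$ratio_thresh * amax & st$area >= abs_min
  pairs <- min(4L, sum(perm) %/% 2L)
  structure(list(permanent_pairs = pairs, age_class = mapping[pairs + 1L],
                 n_regions = nrow(st), areas = st$area),
            class = "tooth_age")
}

#' @export
print.tooth_age <- function(x, ...) {
  cat(sprintf("tooth age: %d permanent pair(s) -> %s (%d regions)\n",
              x$permanent_pairs, x$age_class, x$n_regions))
  invisible(x)
}
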