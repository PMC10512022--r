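# calibration: detect the black-bordered sign with pure R/G/B blocks and
# derive the cm-per-pixel scale and an affine color correction.

#' Detect the calibration sign
#'
#' Finds the best dark-bordered convex quadrilateral whose interior
#' contains three color blocks in red/green/blue dominance order. Corner
#' candidates come from the extreme points of each dark connected
#' component; the candidate is scored by the fraction of its perimeter
#' classified dark (`border_score`).
#'
#' @param image `goat_image` or array.
#' @param config a [goat_config()].
#' @return object of class `sign_detection`: `corners` (4 x 2, clockwise
#'   from top-left), `border_score`, `block_colors` (3 x 3 matrix, rows
#'   red/green/blue), `border_color`, `skew_deg`, `flags`, `sign_mask`.
#'   Errors with `"sign not found"` when no candidate qualifies.
#' @export
detect_sign <- function(image, config = goat_config()) {
  img <- if (inherits(image, "goat_image")) image$pixels else image
  assert_image(img)
  cfg <- config
  nr <- dim(img)[1]; nc <- dim(img)[2]
  hsv <- image_hsv(img)
  dark <- hsv$v <= cfg$sign$dark_value_max
  lab <- label_components(dark)
  st <- component_stats(lab)
  st <- st[st$area >= max(500, 0.002 * nr * nc), , drop = FALSE]
  if (nrow(st) == 0L) stop("sign not found", call. = FALSE)

  best <- NULL
  for (l in st$label) {
    idx <- which(lab == l, arr.ind = TRUE)
    r <- idx[, 1]; cc <- idx[, 2]
    tl <- idx[which.min(r + cc), ]
    br <- idx[which.max(r + cc), ]
    tr <- idx[which.max(cc - r), ]
    bl <- idx[which.max(r - cc), ]
    corners <- rbind(TL = tl, TR = tr, BR = br, BL = bl)
    # degenerate / non-quadrilateral shapes
    if (nrow(unique(corners)) < 4L) next
    area_q <- abs(sum(corners[, 2] * corners[c(2:4, 1), 1] -
                        corners[c(2:4, 1), 2] * corners[, 1])) / 2
    if (area_q < 0.5 * nrow(idx)) next

    # border score: fraction of the quadrilateral perimeter that is dark
    per <- do.call(rbind, lapply(1:4, function(i) {
      segment_pixels(corners[i, ], corners[if (i == 4) 1 else i + 1, ])
    }))
    per <- per[per[, 1] >= 1 & per[, 1] <= nr & per[, 2] >= 1 & per[, 2] <= nc, ]
    bscore <- mean(dark[per])
    if (bscore < cfg$sign$low_conf_border_score) next

    # interior blocks: dominant-channel pixels inside the quadrilateral
    rows <- seq(min(corners[, 1]), max(corners[, 1]))
    cols <- seq(min(corners[, 2]), max(corners[, 2]))
    gR <- as.matrix(expand.grid(row = rows, col = cols))
    ins <- in_convex_poly(gR[, 1], gR[, 2], corners)
    gR <- gR[ins, , drop = FALSE]
    ii <- gR[, 1] + (gR[, 2] - 1L) * nr
    R <- img[ii]; G <- img[ii + nr * nc]; B <- img[ii + 2L * nr * nc]
    dom_r <- R - pmax(G, B) >= 60
    dom_g <- G - pmax(R, B) >= 60
    dom_b <- B - pmax(R, G) >= 60
    if (sum(dom_r) < 100 || sum(dom_g) < 100 || sum(dom_b) < 100) next
    # left-to-right ordering along the top edge direction
    ex <- corners["TR", ] - corners["TL", ]
    proj <- function(sel) mean((gR[sel, 1] - corners["TL", 1]) * ex[1] +
                                 (gR[sel, 2] - corners["TL", 2]) * ex[2])
    if (!(proj(dom_r) < proj(dom_g) && proj(dom_g) < proj(dom_b))) next

    block_colors <- rbind(red = c(mean(R[dom_r]), mean(G[dom_r]), mean(B[dom_r])),
                          green = c(mean(R[dom_g]), mean(G[dom_g]), mean(B[dom_g])),
                          blue = c(mean(R[dom_b]), mean(G[dom_b]), mean(B[dom_b])))
    comp_idx <- idx[, 1] + (idx[, 2] - 1L) * nr
    border_color <- c(mean(img[comp_idx]), mean(img[comp_idx + nr * nc]),
                      mean(img[comp_idx + 2L * nr * nc]))
    skew <- atan2(-(corners["TR", 1] - corners["TL", 1]),
                  corners["TR", 2] - corners["TL", 2]) * 180 / pi
    cand <- list(corners = corners, border_score = bscore,
                 block_colors = block_colors, border_color = border_color,
                 skew_deg = skew, label = l)
    if (is.null(best) || bscore > best$border_score) best <- cand
  }
  if (is.null(best)) stop("sign not found", call. = FALSE)
  flags <- if (best$border_score < cfg$sign$min_border_score) "LOW_CONFIDENCE" else character()
  sign_mask <- matrix(FALSE, nr, nc)
  rows <- seq(min(best$corners[, 1]), max(best$corners[, 1]))
  cols <- seq(min(best$corners[, 2]), max(best$corners[, 2]))
  gR <- as.matrix(expand.grid(row = rows, col = cols))
  ins <- in_convex_poly(gR[, 1], gR[, 2], best$corners)
  sign_mask[gR[ins, , drop = FALSE]] <- TRUE
  structure(list(corners = best$corners, border_score = best$border_score,
                 block_colors = best$block_colors,
                 border_color = best$border_color,
                 skew_deg = best$skew_deg, flags = flags,
                 sign_mask = sign_mask),
            class = "sign_detection")
}

#' @export
print.sign_detection <- function(x, ...) {
  cat(sprintf("sign_detection: border score %.2f, skew %.1f deg%s\n",
              x$border_score, x$skew_deg,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Centimeters-per-pixel scale from a sign detection
#'
#' The scale is the mean of the width-based and height-based estimates
#' after skew correction (edge lengths are rotation-invariant). Pixel
#' extents are corner distances plus one, since corners index the first and
#' last pixel of an edge.
#'
#' @param det a `sign_detection`.
#' @param physical `c(width_cm, height_cm)` of the sign's outer border.
#' @return scale in cm per pixel.
#' @export
spatial_scale <- function(det, physical = with(goat_config()$sign, c(width_cm, height_cm))) {
  co <- det$corners
  el <- function(a, b) sqrt(sum((co[a, ] - co[b, ])^2)) + 1
  top <- el("TL", "TR"); bottom <- el("BL", "BR")
  left <- el("TL", "BL"); right <- el("TR", "BR")
  if (min(top, bottom, left, right) < 5) {
    stop("degenerate sign quadrilateral", call. = FALSE)
  }
  pw <- (top + bottom) / 2
  ph <- (left + right) / 2
  mean(c(physical[1] / pw, physical[2] / ph))
}

#' Estimate an affine color-correction transform from the sign
#'
#' Least-squares affine map (3x3 matrix plus offset) sending the measured
#' border and block colors to their references. With four reference colors
#' the per-channel systems are exactly determined; the residual is the mean
#' per-channel absolute error on those colors. Higher-order models would
#' overfit four references.
#'
#' @param det a `sign_detection`.
#' @param reference 4 x 3 matrix of reference RGB rows in order border
#'   (black), red, green, blue; default from [goat_config()].
#' @return object of class `color_transform`: `M` (3x3), `offset`,
#'   `residual`.
#' @export
estimate_color_transform <- function(det, reference = NULL) {
  cfg <- goat_config()
  if (is.null(reference)) {
    reference <- rbind(cfg$sign$ref_border, cfg$sign$ref_red,
                       cfg$sign$ref_green, cfg$sign$ref_blue)
  }
  measured <- rbind(det$border_color, det$block_colors)
  stopifnot(nrow(measured) == 4L, nrow(reference) == 4L)
  X <- cbind(measured, 1)
  if (qr(X)$rank < 4L) {
    stop("rank-deficient color system: sign block colors are degenerate", call. = FALSE)
  }
  coefs <- solve(X, reference)          # 4 x 3: rows = (R, G, B, 1) weights
  M <- t(coefs[1:3, , drop = FALSE])
  offset <- coefs[4, ]
  fitted <- measured %*% t(M) + rep(offset, each = 4)
  residual <- mean(abs(fitted - reference))
  structure(list(M = M, offset = offset, residual = residual),
            class = "color_transform")
}

#' Identity color transform
#' @return a `color_transform` that leaves colors unchanged.
#' @export
identity_transform <- function() {
  structure(list(M = diag(3), offset = c(0, 0, 0), residual = 0),
            class = "color_transform")
}

#' Apply a color transform to an image or color matrix
#'
#' @param x `[rows, cols, 3]` array, `goat_image`, or n x 3 color matrix.
#' @param transform a `color_transform`.
#' @return same shape as `x`, values clamped to `[0, 255]`.
#' @export
apply_color_transform <- function(x, transform) {
  if (inherits(x, "goat_image")) {
    x$pixels <- apply_color_transform(x$pixels, transform)
    return(x)
  }
  if (is.matrix(x)) {
    return(clamp(x %*% t(transform$M) + rep(transform$offset, each = nrow(x))))
  }
  d <- dim(x)
  m <- cbind(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
  out <- clamp(m %*% t(transform$M) + rep(transform$offset, each = nrow(m)))
  array(c(out), d)
}

#' Full calibration from a sign-view image
#'
#' Convenience wrapper: [detect_sign()], [spatial_scale()] and
#' [estimate_color_transform()] in one call.
#'
#' @param image `goat_image` or array.
#' @param config a [goat_config()].
#' @return object of class `calibration_result`: `scale` (cm/px),
#'   `transform`, `residual`, `source_pose`, `detection`.
#' @export
calibrate_from_sign <- function(image, config = goat_config()) {
  det <- detect_sign(image, config)
  sc <- spatial_scale(det, c(config$sign$width_cm, config$sign$height_cm))
  refs <- rbind(config$sign$ref_border, config$sign$ref_red,
                config$sign$ref_green, config$sign$ref_blue)
  tf <- estimate_color_transform(det, refs)
  structure(list(scale = sc, transform = tf, residual = tf$residual,
                 source_pose = if (inherits(image, "goat_image")) image$pose else NA_character_,
                 detection = det),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration: %.5f cm/px from '%s' pose, color residual %.3f\n",
              x$scale, x$source_pose, x$residual))
  invisible(x)
}
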