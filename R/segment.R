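# segmentation: chroma-key background classification, prior-based subject
# isolation, gradient-snap boundary refinement, QC flags.

#' Classify blue-background pixels
#'
#' Marks a pixel as background iff its hue lies in the configured blue band
#' with saturation and value above the minima. Classification in HSV makes
#' the result invariant to moderate brightness changes, which matters under
#' field lighting shifts.
#'
#' @param image `goat_image` or `[rows, cols, 3]` array.
#' @param thresholds list with `hue` (degrees, `c(lo, hi)`), `s_min`,
#'   `v_min`; default from [goat_config()].
#' @return logical matrix, `TRUE` = background.
#' @export
classify_blue <- function(image, thresholds = goat_config()$blue) {
  img <- if (inherits(image, "goat_image")) image$pixels else image
  assert_image(img)
  hsv <- image_hsv(img)
  hsv$h >= thresholds$hue[1] & hsv$h <= thresholds$hue[2] &
    hsv$s >= thresholds$s_min & hsv$v >= thresholds$v_min
}

new_goat_mask <- function(mask, blue_coverage = NA_real_,
                          occluder_suspected = FALSE, flags = character()) {
  idx <- which(mask, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  structure(list(
    mask = mask,
    component_area = nrow(idx),
    centroid = c(row = mean(idx[, 1]), col = mean(idx[, 2])),
    touches_border = any(idx[, 1] == 1L | idx[, 1] == nr |
                           idx[, 2] == 1L | idx[, 2] == nc),
    occluder_suspected = occluder_suspected,
    blue_coverage = blue_coverage,
    flags = flags), class = "goat_mask")
}

#' @export
print.goat_mask <- function(x, ...) {
  cat(sprintf("goat_mask: %d px, centroid (%.0f, %.0f), blue coverage %.2f%s\n",
              x$component_area, x$centroid[1], x$centroid[2], x$blue_coverage,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Isolate the subject from the background grid
#'
#' Applies the protocol's isolation priors to the non-background connected
#' components (8-connected): the subject has a limited range of size (area
#' within a fraction band of the frame) and stands near the frame center.
#' The largest qualifying component is returned with interior holes filled;
#' ties on area are broken by smaller centroid-to-center distance, then by
#' topmost-leftmost bounding box.
#'
#' @param image `goat_image` or array (used for shape and blue coverage).
#' @param background logical background grid from [classify_blue()].
#' @param priors list `min_area_frac`, `max_area_frac`,
#'   `max_centroid_offset_frac` (fraction of the frame diagonal).
#' @param exclude optional logical mask (e.g. the detected calibration
#'   sign); components mostly inside it are not considered subjects.
#' @return a `goat_mask`.
#' @export
isolate_roi <- function(image, background, priors = goat_config()$priors,
                        exclude = NULL) {
  img <- if (inherits(image, "goat_image")) image$pixels else image
  if (!all(dim(background) == dim(img)[1:2])) {
    stop("background grid does not match image", call. = FALSE)
  }
  nr <- nrow(background); nc <- ncol(background)
  frame_px <- nr * nc
  lab <- label_components(!background)
  st <- component_stats(lab)
  if (!is.null(exclude)) {
    ov <- vapply(st$label, function(l) {
      sel <- lab == l
      sum(sel & exclude) / sum(sel)
    }, 0)
    st <- st[ov <= 0.5, , drop = FALSE]
  }
  diag_px <- sqrt(nr^2 + nc^2)
  off <- sqrt((st$crow - (nr + 1) / 2)^2 + (st$ccol - (nc + 1) / 2)^2)
  ok <- st$area >= priors$min_area_frac * frame_px &
        st$area <= priors$max_area_frac * frame_px &
        off <= priors$max_centroid_offset_frac * diag_px
  cand <- st[ok, , drop = FALSE]
  if (nrow(cand) == 0L) {
    cond <- structure(class = c("goatpheno_no_subject", "error", "condition"),
                      list(message = "no subject found: no component satisfies the size/centering priors",
                           call = sys.call(), candidates = st))
    stop(cond)
  }
  cand$off <- off[ok]
  o <- order(-cand$area, cand$off, cand$rmin, cand$cmin)
  pick <- cand[o[1], ]
  mask <- fill_holes(lab == pick$label)
  blue_cov <- mean(background[!mask])
  new_goat_mask(mask, blue_coverage = blue_cov)
}

#' Refine a mask boundary by gradient snapping
#'
#' Repositions the silhouette boundary to the maximum color-gradient
#' location along the local boundary normal, searching within
#' `window_px` either side. Every pixel within the search band is
#' reclassified by where the strongest color step along its normal lies, so
#' the boundary never moves farther than the window. If refinement breaks
#' the component, the unrefined mask is returned with a `REFINE_FALLBACK`
#' flag.
#'
#' @param image `goat_image` or array.
#' @param mask `goat_mask` or logical matrix.
#' @param window_px search half-width in pixels.
#' @param min_grad minimum color-step magnitude (sum of absolute channel
#'   differences) for an edge to count; flat neighborhoods keep their
#'   original label.
#' @return a `goat_mask`.
#' @export
refine_edges <- function(image, mask, window_px = goat_config()$refine$window_px,
                         min_grad = goat_config()$refine$min_grad) {
  img_full <- if (inherits(image, "goat_image")) image$pixels else image
  m_full <- if (inherits(mask, "goat_mask")) mask$mask else mask
  prev <- if (inherits(mask, "goat_mask")) mask else new_goat_mask(m_full)
  stopifnot(all(dim(m_full) == dim(img_full)[1:2]))
  w <- as.integer(window_px)

  # all work happens within the mask bounding box plus the search margin
  idx_f <- which(m_full, arr.ind = TRUE)
  if (nrow(idx_f) == 0L) return(prev)
  pad <- w + 6L
  rw <- max(1L, min(idx_f[, 1]) - pad):min(nrow(m_full), max(idx_f[, 1]) + pad)
  cl <- max(1L, min(idx_f[, 2]) - pad):min(ncol(m_full), max(idx_f[, 2]) + pad)
  m0 <- m_full[rw, cl, drop = FALSE]
  img <- img_full[rw, cl, , drop = FALSE]
  nr <- nrow(m0); nc <- ncol(m0)

  din <- mask_distmap(m0)       # distance to background (0 outside)
  dout <- mask_distmap(!m0)     # distance to foreground (0 inside)
  band <- (m0 & din <= w + 1) | (!m0 & dout <= w + 1)
  idx <- which(band)
  if (length(idx) == 0L) return(prev)

  # outward normal from the smoothed mask (gradient points inward)
  sm <- t(EBImage::imageData(EBImage::gblur(t(m0 * 1), sigma = 2)))
  gr <- matrix(0, nr, nc); gc <- matrix(0, nr, nc)
  gr[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  gc[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  nrm <- sqrt(gr[idx]^2 + gc[idx]^2)
  good <- nrm > 1e-6
  pr <- (idx - 1L) %% nr + 1L
  pc <- (idx - 1L) %/% nr + 1L
  nr_r <- -gr[idx] / pmax(nrm, 1e-12)   # outward
  nr_c <- -gc[idx] / pmax(nrm, 1e-12)

  sample_rgb <- function(t) {
    sr <- pmin(pmax(round(pr + t * nr_r), 1L), nr)
    sc <- pmin(pmax(round(pc + t * nr_c), 1L), nc)
    ii <- sr + (sc - 1L) * nr
    cbind(img[ii], img[ii + nr * nc], img[ii + 2L * nr * nc])
  }

  best_s <- rep(min_grad - 1e-9, length(idx))
  best_t <- rep(NA_integer_, length(idx))
  prev_rgb <- sample_rgb(-w)
  for (t in (-w):(w - 1L)) {
    cur_rgb <- sample_rgb(t + 1L)
    s <- rowSums(abs(cur_rgb - prev_rgb))
    upd <- s > best_s
    best_s[upd] <- s[upd]
    best_t[upd] <- t
    prev_rgb <- cur_rgb
  }

  newv <- m0[idx]
  decided <- good & !is.na(best_t)
  # the strongest step between offsets t and t+1 is the boundary: a pixel is
  # foreground iff that step lies at or beyond it along its outward normal
  newv[decided] <- best_t[decided] >= 0L
  m1 <- m0
  m1[idx] <- newv

  lab <- label_components(m1)
  st <- component_stats(lab)
  if (nrow(st) == 0L) {
    prev$flags <- union(prev$flags, "REFINE_FALLBACK")
    return(prev)
  }
  keep <- st$label[which.max(st$area)]
  m1 <- fill_holes(lab == keep)
  if (sum(m1) < 0.5 * sum(m0)) {
    prev$flags <- union(prev$flags, "REFINE_FALLBACK")
    return(prev)
  }
  out_full <- matrix(FALSE, nrow(m_full), ncol(m_full))
  out_full[rw, cl] <- m1
  new_goat_mask(out_full, blue_coverage = prev$blue_coverage,
                occluder_suspected = prev$occluder_suspected,
                flags = prev$flags)
}

#' Scene quality-control flags
#'
#' Emits coded warnings for the field failure modes the protocol documents:
#' dirty or missing tarp (`LOW_BLUE_COVERAGE`), subject clipped by the frame
#' (`SUBJECT_TOUCHES_BORDER`), a foreign non-blue object close to the
#' subject such as a handler limb or rock (`NON_BLUE_OBJECT_NEAR_SUBJECT`),
#' and feet not reaching the expected ground line, e.g. hidden behind rocks
#' (`FEET_NOT_ON_GROUND_LINE`). QC never raises an error.
#'
#' @param image `goat_image` or array.
#' @param mask `goat_mask` or logical matrix.
#' @param config a [goat_config()].
#' @param sign_mask optional logical mask of the detected calibration sign,
#'   excluded from the foreign-object check.
#' @return character vector of flag codes (possibly empty).
#' @export
qc_scene <- function(image, mask, config = goat_config(), sign_mask = NULL) {
  img <- if (inherits(image, "goat_image")) image$pixels else image
  m <- if (inherits(mask, "goat_mask")) mask$mask else mask
  qc <- config$qc
  flags <- character()
  bg <- classify_blue(img, config$blue)
  blue_cov <- mean(bg[!m])
  if (!is.na(blue_cov) && blue_cov < qc$min_blue_coverage) {
    flags <- c(flags, "LOW_BLUE_COVERAGE")
  }
  nr <- nrow(m); nc <- ncol(m)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(flags, "EMPTY_MASK"))
  if (any(idx[, 1] == 1L | idx[, 1] == nr | idx[, 2] == 1L | idx[, 2] == nc)) {
    flags <- c(flags, "SUBJECT_TOUCHES_BORDER")
  }
  # foreign non-blue components near the subject
  other <- !bg & !m
  if (!is.null(sign_mask)) other <- other & !dilate_mask(sign_mask, 2L)
  lab <- label_components(other)
  st <- component_stats(lab)
  st <- st[st$area >= qc$near_min_px, , drop = FALSE]
  if (nrow(st) > 0L) {
    bb <- c(rmin = min(idx[, 1]), rmax = max(idx[, 1]),
            cmin = min(idx[, 2]), cmax = max(idx[, 2]))
    gap_r <- pmax(0, pmax(st$rmin - bb["rmax"], bb["rmin"] - st$rmax))
    gap_c <- pmax(0, pmax(st$cmin - bb["cmax"], bb["cmin"] - st$cmax))
    if (any(pmax(gap_r, gap_c) <= qc$near_dist_px)) {
      flags <- c(flags, "NON_BLUE_OBJECT_NEAR_SUBJECT")
    }
  }
  expected_ground <- qc$ground_row_frac * nr
  tol <- qc$ground_tol_frac * nr
  if (max(idx[, 1]) < expected_ground - tol) {
    flags <- c(flags, "FEET_NOT_ON_GROUND_LINE")
  }
  flags
}
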