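# morphometry: calibrated body measures from the sign-view (side) and
# rear-view masks. The protocol needs only those two poses for measures;
# landmarks are located by fractional silhouette bands because the final
# protocol abandoned physical bone marking.

#' Body-measure container
#'
#' @param HW,BL,chest_depth,chest_width,CG,BW measures in cm (BW kg);
#'   `NA` when not available.
#' @param flags per-measure confidence/warning codes.
#' @return object of class `body_measures`.
#' @export
body_measures <- function(HW = NA_real_, BL = NA_real_, chest_depth = NA_real_,
                          chest_width = NA_real_, CG = NA_real_, BW = NA_real_,
                          flags = character()) {
  vals <- c(HW = HW, BL = BL, chest_depth = chest_depth,
            chest_width = chest_width, CG = CG, BW = BW)
  if (any(!is.na(vals) & vals <= 0 & names(vals) != "BW")) {
    stop("computed measures must be positive", call. = FALSE)
  }
  if (!is.na(CG) && !is.na(chest_depth) && !is.na(chest_width) &&
      CG > pi * (chest_depth + chest_width) + 1e-9) {
    stop("chest girth exceeds the elliptical perimeter bound", call. = FALSE)
  }
  structure(as.list(vals), flags = flags, class = "body_measures")
}

#' @export
print.body_measures <- function(x, ...) {
  f <- function(v, u) if (is.na(v)) "-" else sprintf("%.1f %s", v, u)
  cat(sprintf("HW %s | BL %s | depth %s | width %s | CG %s | BW %s\n",
              f(x$HW, "cm"), f(x$BL, "cm"), f(x$chest_depth, "cm"),
              f(x$chest_width, "cm"), f(x$CG, "cm"), f(x$BW, "kg")))
  invisible(x)
}

mask_matrix <- function(mask) if (inherits(mask, "goat_mask")) mask$mask else mask

# column-wise profiles of a mask: top row, bottom row per column with pixels
mask_profiles <- function(m) {
  cols <- which(colSums(m) > 0)
  top <- apply(m[, cols, drop = FALSE], 2, function(v) which(v)[1])
  bot <- apply(m[, cols, drop = FALSE], 2, function(v) tail(which(v), 1))
  list(cols = cols, top = top, bot = bot)
}

#' Ground row of a standing subject
#'
#' The ground line is estimated from the leg extremities: contiguous column
#' groups whose silhouette reaches into the lowest part of the mask are
#' treated as legs, and the ground row is the median of the two lowest leg
#' extremes — robust to one lifted or shortened foot.
#'
#' @param mask `goat_mask` or logical matrix; must not touch the bottom
#'   frame border.
#' @return pixel row index of the ground line.
#' @export
ground_row <- function(mask) {
  m <- mask_matrix(mask)
  pr <- mask_profiles(m)
  if (length(pr$cols) == 0L) stop("empty mask", call. = FALSE)
  rmin <- min(pr$top); rmax <- max(pr$bot)
  h <- rmax - rmin + 1L
  deep <- pr$bot >= rmin + 0.80 * h
  if (!any(deep)) stop("legs not resolved", call. = FALSE)
  # contiguous column groups of deep-reaching columns
  dc <- pr$cols[deep]
  grp <- cumsum(c(1L, diff(dc) > 3L))
  extremes <- vapply(split(seq_along(dc), grp), function(i) max(pr$bot[deep][i]), 0)
  if (length(extremes) < 2L) stop("legs not resolved", call. = FALSE)
  lowest2 <- sort(extremes, decreasing = TRUE)[1:2]
  round(mean(lowest2))
}

# orientation: the head end's extreme column has its mask bottom high above
# the ground (no leg under the muzzle); the rear extreme column carries the
# hind leg. Returns TRUE when the subject faces right.
faces_right <- function(m) {
  pr <- mask_profiles(m)
  n <- length(pr$cols)
  k <- max(3L, round(0.02 * n))
  rmin <- min(pr$top); rmax <- max(pr$bot)
  left_bot <- mean(pr$bot[seq_len(k)])
  right_bot <- mean(pr$bot[(n - k + 1L):n])
  right_bot < left_bot  # higher bottom (smaller row) = head end
}

# exclude columns ahead of the neck inflection when the head crests above
# the topline window; returns the columns (ascending) of the body
body_columns <- function(m) {
  pr <- mask_profiles(m)
  gr <- tryCatch(ground_row(m), error = function(e) max(pr$bot))
  h <- gr - pr$top   # height profile in px above ground
  n <- length(pr$cols)
  # front = rightmost columns (right-facing convention)
  win <- seq(from = n, by = -1L, length.out = max(5L, round(0.35 * n)))
  hw_s <- stats::filter(h, rep(1 / 5, 5), sides = 2)
  hw_s[is.na(hw_s)] <- h[is.na(hw_s)]
  hwin <- hw_s[win]
  m1 <- which.max(hwin)                     # candidate head crest
  if (m1 < length(win)) {
    after <- hwin[seq(m1, length(win))]
    m2 <- m1 + which.min(after) - 1L
    if (hwin[m2] < 0.95 * hwin[m1] && m2 > m1) {
      cut_col <- pr$cols[win[m2]]
      return(pr$cols[pr$cols <= cut_col])
    }
  }
  pr$cols
}

#' Height at withers
#'
#' Locates the withers as the topline maximum within the band above the
#' forelegs (front 20-45 percent of the body span, head columns excluded
#' ahead of the neck inflection) and reports the perpendicular distance
#' from the ground line, in cm.
#'
#' @param mask `goat_mask` or logical matrix (side/sign view, subject
#'   facing right; left-facing masks are mirrored with a flag).
#' @param scale cm per pixel (> 0).
#' @param ground ground row; computed by [ground_row()] when `NULL`.
#' @param bands config band list (see [goat_config()]).
#' @return list `HW` (cm), `withers` (row, col), `ground_row`, `flags`.
#' @export
height_at_withers <- function(mask, scale, ground = NULL,
                              bands = goat_config()$bands) {
  stopifnot(scale > 0)
  m <- mask_matrix(mask)
  flags <- character()
  if (!faces_right(m)) {
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    flags <- c(flags, "MIRRORED")
  }
  if (is.null(ground)) ground <- ground_row(m)
  cols <- body_columns(m)
  if (length(cols) < 10L) stop("topline extraction failed: mask too narrow", call. = FALSE)
  span <- max(cols) - min(cols) + 1L
  front <- max(cols)
  band <- cols[cols <= front - bands$withers_front[1] * span &
               cols >= front - bands$withers_front[2] * span]
  if (length(band) == 0L) stop("topline extraction failed: empty withers band", call. = FALSE)
  sub <- m[, band, drop = FALSE]
  tops <- apply(sub, 2, function(v) which(v)[1])
  j <- which.min(tops)
  withers_row <- tops[j]
  list(HW = (ground - withers_row) * scale,
       withers = c(row = withers_row, col = band[j]),
       ground_row = ground, flags = flags)
}

#' Body length
#'
#' Point of shoulder = foremost mask pixel within the chest height band
#' (45-75 percent of body height above the ground); pin point = rearmost
#' pixel in the same band. BL is the Euclidean pixel distance times scale.
#' Among tied extreme-column pixels the one nearest the band center is
#' used, so the measure tracks the horizontal body axis.
#'
#' @inheritParams height_at_withers
#' @return list `BL` (cm), `shoulder` (row, col), `pin` (row, col), `flags`.
#' @export
body_length <- function(mask, scale, ground = NULL,
                        bands = goat_config()$bands) {
  stopifnot(scale > 0)
  m <- mask_matrix(mask)
  flags <- character()
  if (!faces_right(m)) {
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    flags <- c(flags, "MIRRORED")
  }
  if (is.null(ground)) ground <- ground_row(m)
  pr <- mask_profiles(m)
  rmin <- min(pr$top)
  H <- ground - rmin + 1L
  r_lo <- ground - bands$length_height[1] * H   # lower band edge (larger row)
  r_hi <- ground - bands$length_height[2] * H
  rows_band <- seq(max(1L, floor(r_hi)), ceiling(r_lo))
  sub <- m[rows_band, , drop = FALSE]
  cols_in <- which(colSums(sub) > 0)
  if (length(cols_in) == 0L) stop("chest band empty", call. = FALSE)
  mid <- (r_lo + r_hi) / 2
  pick <- function(col) {
    rws <- rows_band[which(sub[, col])]
    rws[which.min(abs(rws - mid))]
  }
  c_front <- max(cols_in); c_rear <- min(cols_in)
  shoulder <- c(row = pick(c_front), col = c_front)
  pin <- c(row = pick(c_rear), col = c_rear)
  bl_px <- sqrt(sum((shoulder - pin)^2))
  list(BL = bl_px * scale, shoulder = shoulder, pin = pin, flags = flags)
}

# columns whose silhouette reaches near the ground (legs)
leg_columns <- function(m, ground) {
  pr <- mask_profiles(m)
  rmin <- min(pr$top)
  H <- ground - rmin + 1L
  pr$cols[pr$bot >= rmin + 0.85 * H]
}

#' Chest depth (side view)
#'
#' Maximum vertical silhouette extent over the column band just behind the
#' forelegs (leg columns excluded), times scale.
#'
#' @inheritParams height_at_withers
#' @return depth in cm.
#' @export
chest_depth <- function(mask, scale, ground = NULL,
                        bands = goat_config()$bands) {
  stopifnot(scale > 0)
  m <- mask_matrix(mask)
  if (!faces_right(m)) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (is.null(ground)) ground <- ground_row(m)
  pr <- mask_profiles(m)
  span <- max(pr$cols) - min(pr$cols) + 1L
  legs <- leg_columns(m, ground)
  cand <- setdiff(pr$cols, legs)
  front_nonleg <- max(cand)
  band <- cand[cand >= front_nonleg - bands$depth_back * span]
  if (length(band) == 0L) stop("depth band empty", call. = FALSE)
  sel <- match(band, pr$cols)
  ext <- pr$bot[sel] - pr$top[sel] + 1L
  max(ext) * scale
}

#' Chest width (rear view)
#'
#' Maximum horizontal silhouette extent within the barrel band of the rear
#' mask (upper portion of the mask, excluding the lowest leg rows), times
#' scale.
#'
#' @inheritParams height_at_withers
#' @return width in cm.
#' @export
chest_width <- function(mask, scale, bands = goat_config()$bands) {
  stopifnot(scale > 0)
  m <- mask_matrix(mask)
  rows_in <- which(rowSums(m) > 0)
  if (length(rows_in) == 0L) stop("empty mask", call. = FALSE)
  rmin <- min(rows_in); H <- max(rows_in) - rmin + 1L
  band <- rows_in[rows_in <= rmin + bands$rear_barrel[2] * H &
                  rows_in >= rmin + bands$rear_barrel[1] * H]
  if (length(band) == 0L) stop("barrel band empty", call. = FALSE)
  widths <- vapply(band, function(r) {
    cc <- which(m[r, ])
    max(cc) - min(cc) + 1L
  }, 0L)
  max(widths) * scale
}

#' Chest girth from depth and width
#'
#' Models the chest cross-section as an ellipse with axes equal to the
#' side-view depth and rear-view width, and returns its perimeter by
#' Ramanujan's second approximation:
#' \deqn{P = \pi (a + b) \left(1 + \frac{3h}{10 + \sqrt{4 - 3h}}\right),
#'       \quad h = \left(\frac{a - b}{a + b}\right)^2}
#' with semi-axes \eqn{a = depth/2}, \eqn{b = width/2}. The approximation
#' is accurate to far better than 0.1 percent for axis ratios up to 3.
#'
#' @param depth chest depth, cm (> 0).
#' @param width chest width, cm (> 0).
#' @return girth (ellipse perimeter), cm.
#' @export
chest_girth <- function(depth, width) {
  if (any(is.na(c(depth, width))) || depth <= 0 || width <= 0) {
    stop("depth and width must be positive", call. = FALSE)
  }
  a <- depth / 2; b <- width / 2
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Predict body weight from body measures
#'
#' Applies a configured formula combining chest girth (CG), body length
#' (BL) and/or height at withers (HW). Built-in formulas:
#' \describe{
#'   \item{cg2bl}{`BW = CG^2 * BL / k` (cm, kg); default `k = 10838`, the
#'     classic girth-squared-times-length rule expressed in metric units.}
#'   \item{power}{`BW = a * CG^p_cg * BL^p_bl * HW^p_hw`.}
#'   \item{linear}{`BW = b0 + b_cg*CG + b_bl*BL + b_hw*HW`.}
#' }
#'
#' @param measures a `body_measures`.
#' @param formula list with `formula` name and its coefficients
#'   (default [goat_config()]`$weight`).
#' @return list `BW` (kg or `NA`), `formula`, `flags`.
#' @export
predict_weight <- function(measures, formula = goat_config()$weight) {
  name <- formula$formula
  need <- switch(name,
                 cg2bl = c("CG", "BL"),
                 power = c("CG", "BL", "HW")[c(formula$p_cg %||% 2,
                                               formula$p_bl %||% 1,
                                               formula$p_hw %||% 0) != 0],
                 linear = c("CG", "BL", "HW")[c(formula$b_cg %||% 0,
                                                formula$b_bl %||% 0,
                                                formula$b_hw %||% 0) != 0],
                 stop("unknown weight formula: ", name, call. = FALSE))
  have <- vapply(need, function(n) !is.na(measures[[n]] %||% NA_real_), TRUE)
  if (!all(have)) {
    return(list(BW = NA_real_, formula = name,
                flags = paste0("BW_MISSING_", need[!have])))
  }
  bw <- switch(name,
    cg2bl = measures$CG^2 * measures$BL / (formula$k %||% 10838),
    power = (formula$a %||% 1) *
      (if (is.na(measures$CG)) 1 else measures$CG^(formula$p_cg %||% 2)) *
      (if (is.na(measures$BL)) 1 else measures$BL^(formula$p_bl %||% 1)) *
      (if (is.na(measures$HW)) 1 else measures$HW^(formula$p_hw %||% 0)),
    linear = (formula$b0 %||% 0) +
      (formula$b_cg %||% 0) * (if (is.na(measures$CG)) 0 else measures$CG) +
      (formula$b_bl %||% 0) * (if (is.na(measures$BL)) 0 else measures$BL) +
      (formula$b_hw %||% 0) * (if (is.na(measures$HW)) 0 else measures$HW))
  list(BW = bw, formula = name, flags = character())
}

#' Digital-vs-manual measure validation
#'
#' Pearson product-moment correlation per measure over paired complete
#' cases, matching animals by `sample_id`.
#'
#' @param digital,manual data.frames with `sample_id` and any of `HW`,
#'   `BL`, `CG`, `chest_depth`, `chest_width`, `BW` columns.
#' @param measures which measures to correlate (defaults to the columns
#'   present in both tables).
#' @return data.frame with columns `measure`, `n`, `r`; `r` is `NA` when a
#'   vector has zero variance or fewer than 3 pairs exist.
#' @export
validate_measures <- function(digital, manual, measures = NULL) {
  stopifnot("sample_id" %in% names(digital), "sample_id" %in% names(manual))
  if (is.null(measures)) {
    measures <- setdiff(intersect(names(digital), names(manual)), "sample_id")
  }
  mg <- merge(digital, manual, by = "sample_id", suffixes = c(".d", ".m"))
  out <- lapply(measures, function(ms) {
    x <- mg[[paste0(ms, ".d")]]; y <- mg[[paste0(ms, ".m")]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    r <- if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) NA_real_
         else stats::cor(x[ok], y[ok])
    data.frame(measure = ms, n = n, r = r)
  })
  do.call(rbind, out)
}
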