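# synthetic_scene: deterministic protocol-compliant scene renderer with
# exact ground truth. Geometry is built in centimeters on the subject plane
# (camera >= 3 m, eye level, sign in plane: perspective treated as a single
# scale) and rasterized at `pixels_per_cm`. Pixel (r, c) samples the point
# x = (c - center_col) / ppcm (cm, rightward), y = (ground_row - r) / ppcm
# (cm, upward); regions are half-open in cm so a W-cm feature spans exactly
# W * ppcm pixels.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  force(expr)
}

DEFECTS <- c("handler_occluder", "rocks", "dirty_tarp", "lighting_shift",
             "missing_ground_tarp", "skewed_sign")

#' Synthetic scene parameters
#'
#' Bundles the goat dimensions, coat, pose, camera geometry and injected
#' field defects for [generate_scene()].
#'
#' @param hw height at withers, cm.
#' @param bl body length (point of shoulder to pin bone), cm.
#' @param chest_depth side-view chest depth, cm; must not exceed `hw`.
#' @param chest_width rear-view chest width, cm.
#' @param pose one of `"sign"`, `"side"`, `"rear"`.
#' @param coat_colors list of 1-3 RGB triplets (goats carry no blue).
#' @param pattern `"solid"` or `"patched"`.
#' @param pattern_fracs pixel fractions per coat color (patched coats);
#'   must sum to 1.
#' @param defects character vector drawn from `handler_occluder`, `rocks`,
#'   `dirty_tarp`, `lighting_shift`, `missing_ground_tarp`, `skewed_sign`.
#' @param seed integer; scenes are bit-identical given identical params.
#' @param camera list: `distance_m` (>= 3 per protocol) and optional
#'   `pixels_per_cm` overriding the config value.
#' @param lighting_gain channel gain used when the `lighting_shift` defect
#'   is active (`NULL` = drawn from `[0.7, 1.3]` under `seed`).
#' @param occluder_style `"skin"` or `"blue"` handler occluder.
#' @param head_y_frac head-center height as a fraction of `hw`.
#' @return list of class `scene_params`.
#' @export
scene_params <- function(hw = 60, bl = 70, chest_depth = 30, chest_width = 20,
                         pose = "sign", coat_colors = NULL, pattern = "solid",
                         pattern_fracs = NULL, defects = character(),
                         seed = 1L, camera = list(distance_m = 3.0),
                         lighting_gain = NULL, occluder_style = "skin",
                         head_y_frac = 0.90) {
  stopifnot(hw > 0, bl > 0, chest_depth > 0, chest_width > 0)
  if (chest_depth > hw) stop("chest_depth must not exceed height at withers", call. = FALSE)
  if ((camera$distance_m %||% 3.0) < 3.0) {
    stop("camera distance must be at least 3 m", call. = FALSE)
  }
  stopifnot(pose %in% c("sign", "side", "rear"))
  bad <- setdiff(defects, DEFECTS)
  if (length(bad)) stop("unknown defects: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(coat_colors)) coat_colors <- list(c(196, 160, 110))
  if (!is.list(coat_colors)) coat_colors <- list(coat_colors)
  stopifnot(length(coat_colors) >= 1, length(coat_colors) <= 3)
  if (pattern == "patched" && is.null(pattern_fracs)) {
    pattern_fracs <- rep(1 / length(coat_colors), length(coat_colors))
  }
  if (pattern == "solid") pattern_fracs <- 1
  stopifnot(abs(sum(pattern_fracs) - 1) < 1e-9)
  structure(list(hw = hw, bl = bl, chest_depth = chest_depth,
                 chest_width = chest_width, pose = pose,
                 coat_colors = coat_colors, pattern = pattern,
                 pattern_fracs = pattern_fracs, defects = defects,
                 seed = as.integer(seed), camera = camera,
                 lighting_gain = lighting_gain,
                 occluder_style = occluder_style,
                 head_y_frac = head_y_frac),
            class = "scene_params")
}

# side-view silhouette in cm coordinates; rasterized over its bounding
# window only. Returns the sub-window mask + landmark geometry.
side_goat_mask <- function(p, xoff, ground_row, center_col, ppcm, nr, nc) {
  hw <- p$hw; bl <- p$bl; depth <- p$chest_depth
  a <- bl / 2; b <- depth / 2
  yc <- hw - depth / 2
  legw0 <- max(3.5, 0.07 * bl)
  ry0 <- min(0.06 * bl, 0.09 * hw)
  rx0 <- 1.7 * ry0
  xh0 <- xoff + a + 1.2 * rx0
  y_hi <- max(hw, p$head_y_frac * hw + ry0) + 1
  rw <- max(1L, floor(ground_row - y_hi * ppcm)):min(nr, ground_row)
  cl <- max(1L, floor(center_col + (xoff - a - legw0 - 3) * ppcm)):
        min(nc, ceiling(center_col + (xh0 + rx0 + 2) * ppcm))
  X <- matrix((cl - center_col) / ppcm, length(rw), length(cl), byrow = TRUE)
  Y <- matrix((ground_row - rw) / ppcm, length(rw), length(cl))
  trunk <- (abs((X - xoff) / a))^4 + (abs((Y - yc) / b))^4 <= 1
  legw <- max(3.5, 0.07 * bl)
  # front leg's leading edge closed at the shoulder column, so the leg and
  # the trunk tip share the same foremost pixel column
  legs <- (X > xoff + a - legw & X <= xoff + a & Y >= 0 & Y < yc) |
    (X >= xoff - a & X < xoff - a + legw & Y >= 0 & Y < yc) |
    (X > xoff + a - legw - 2 & X <= xoff + a - 2 & Y >= 0.4 & Y < yc) |
    (X >= xoff - a + 2 & X < xoff - a + legw + 2 & Y >= 0.4 & Y < yc)
  ry <- min(0.06 * bl, 0.09 * hw)
  rx <- 1.7 * ry
  yh <- p$head_y_frac * hw
  xh <- xoff + a + 1.2 * rx
  head <- ((X - xh) / rx)^2 + ((Y - yh) / ry)^2 <= 1
  # neck: capsule from trunk top-front to the head
  p1 <- c(xoff + 0.6 * a, hw - 0.2 * depth)
  p2 <- c(xh - 0.5 * rx, yh)
  nw <- min(0.85 * ry, 0.15 * depth)
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  t <- pmin(1, pmax(0, ((X - p1[1]) * vx + (Y - p1[2]) * vy) / (vx^2 + vy^2)))
  neck <- (X - (p1[1] + t * vx))^2 + (Y - (p1[2] + t * vy))^2 <= nw^2
  list(mask = trunk | legs | head | neck, rw = rw, cl = cl,
       shoulder_cm = c(xoff + a, yc), pin_cm = c(xoff - a, yc),
       withers_cm = c(xoff, hw), span_cm = c(xoff - a, xh + rx))
}

rear_goat_mask <- function(p, xoff, ground_row, center_col, ppcm, nr, nc) {
  hw <- p$hw; depth <- p$chest_depth; w <- p$chest_width
  yc <- hw - depth / 2
  rw <- max(1L, floor(ground_row - (hw + 1) * ppcm)):min(nr, ground_row)
  cl <- max(1L, floor(center_col + (xoff - w / 2 - 2) * ppcm)):
        min(nc, ceiling(center_col + (xoff + w / 2 + 2) * ppcm))
  X <- matrix((cl - center_col) / ppcm, length(rw), length(cl), byrow = TRUE)
  Y <- matrix((ground_row - rw) / ppcm, length(rw), length(cl))
  trunk <- ((X - xoff) / (w / 2))^2 + ((Y - yc) / (depth / 2))^2 <= 1
  legw <- max(2.5, 0.20 * w)
  leg <- function(x0) X >= x0 & X < x0 + legw & Y >= 0 & Y < yc
  legs <- leg(xoff - w / 2 + 0.05 * w) | leg(xoff + w / 2 - legw - 0.05 * w)
  list(mask = trunk | legs, rw = rw, cl = cl, width_cm = w)
}

# sign geometry: outer rectangle snapped to the pixel grid, optional skew
sign_geometry <- function(cfg, ppcm, x_left, y_center, skew_deg = 0) {
  W <- cfg$sign$width_cm; H <- cfg$sign$height_cm
  x0 <- round(x_left * ppcm) / ppcm
  y0 <- round((y_center - H / 2) * ppcm) / ppcm
  list(W = W, H = H, border = cfg$sign$border_cm,
       x0 = x0, y0 = y0, skew = skew_deg * pi / 180,
       cx = x0 + W / 2, cy = y0 + H / 2)
}

# paints the sign onto img (in place via return); returns corner pixel
# coords (clockwise from top-left) and block/interior info. Rasterization is
# restricted to the sign's bounding window for speed.
render_sign <- function(img, sg, cfg, ground_row, center_col, ppcm) {
  nr <- dim(img)[1]; nc <- dim(img)[2]
  half <- sqrt(sg$W^2 + sg$H^2) / 2 + 2
  rw <- max(1L, floor(ground_row - (sg$cy + half) * ppcm)):
        min(nr, ceiling(ground_row - (sg$cy - half) * ppcm))
  cl <- max(1L, floor(center_col + (sg$cx - half) * ppcm)):
        min(nc, ceiling(center_col + (sg$cx + half) * ppcm))
  X <- matrix((cl - center_col) / ppcm, length(rw), length(cl), byrow = TRUE)
  Y <- matrix((ground_row - rw) / ppcm, length(rw), length(cl))
  # rotate scene coords into the sign frame
  ca <- cos(sg$skew); sa <- sin(sg$skew)
  Xr <- sg$cx + ca * (X - sg$cx) + sa * (Y - sg$cy)
  Yr <- sg$cy - sa * (X - sg$cx) + ca * (Y - sg$cy)
  outer <- Xr >= sg$x0 & Xr < sg$x0 + sg$W & Yr >= sg$y0 & Yr < sg$y0 + sg$H
  b <- sg$border
  inner <- Xr >= sg$x0 + b & Xr < sg$x0 + sg$W - b &
           Yr >= sg$y0 + b & Yr < sg$y0 + sg$H - b
  # three pure blocks, left to right R G B, in the lower interior
  wi <- sg$W - 2 * b
  gap <- 1.5
  bw <- (wi - 4 * gap) / 3
  bh <- min(10, sg$H - 2 * b - 2)
  refs <- list(cfg$sign$ref_red, cfg$sign$ref_green, cfg$sign$ref_blue)
  block_masks <- vector("list", 3)
  for (k in 1:3) {
    bx0 <- sg$x0 + b + gap + (k - 1) * (bw + gap)
    by0 <- sg$y0 + b + 1
    block_masks[[k]] <- Xr >= bx0 & Xr < bx0 + bw & Yr >= by0 & Yr < by0 + bh
  }
  for (ch in 1:3) {
    pl <- img[, , ch]
    sub <- pl[rw, cl, drop = FALSE]
    sub[outer] <- cfg$sign$ref_border[ch]
    sub[inner] <- cfg$sign$interior_rgb[ch]
    for (k in 1:3) sub[block_masks[[k]]] <- refs[[k]][ch]
    pl[rw, cl] <- sub
    img[, , ch] <- pl
  }
  # corner pixel coordinates, clockwise from top-left (outer edge).
  # Half-open rendering: the far edges (right, bottom in sign frame) sit one
  # pixel inside the continuous corner position.
  if (abs(sg$skew) < 1e-9) {
    r_top <- ground_row - (sg$y0 + sg$H) * ppcm + 1
    r_bot <- ground_row - sg$y0 * ppcm
    c_left <- center_col + sg$x0 * ppcm
    c_right <- center_col + (sg$x0 + sg$W) * ppcm - 1
    corn <- rbind(c(r_top, c_left), c(r_top, c_right),
                  c(r_bot, c_right), c(r_bot, c_left))
  } else {
    cs <- rbind(c(sg$x0, sg$y0 + sg$H), c(sg$x0 + sg$W, sg$y0 + sg$H),
                c(sg$x0 + sg$W, sg$y0), c(sg$x0, sg$y0))  # TL TR BR BL in cm
    corn <- t(apply(cs, 1, function(pt) {
      x <- sg$cx + ca * (pt[1] - sg$cx) - sa * (pt[2] - sg$cy)
      y <- sg$cy + sa * (pt[1] - sg$cx) + ca * (pt[2] - sg$cy)
      c(ground_row - y * ppcm, center_col + x * ppcm)
    }))
    corn <- round(corn)
  }
  dimnames(corn) <- list(c("TL", "TR", "BR", "BL"), c("row", "col"))
  sign_mask <- matrix(FALSE, nr, nc)
  sign_mask[rw, cl] <- outer
  list(img = img, corners = corn, sign_mask = sign_mask)
}

#' Generate a synthetic protocol scene with exact ground truth
#'
#' Renders a parametric goat silhouette (superellipse trunk, neck, head,
#' four legs) against the blue backdrop and ground tarp, adds the
#' black-bordered calibration sign for sign/rear poses (the side "naked"
#' view has no sign), injects the requested field defects, and returns both
#' the image and the exact ground truth (mask, scale, landmarks, measures,
#' defect inventory).
#'
#' @param params a [scene_params()] object.
#' @param config a [goat_config()] list.
#' @return list with elements `image` (a `goat_image`) and `truth`
#'   (mask, scale cm/px, withers/shoulder/pin points, `ground_row`,
#'   `sign_corners`, `measures`, `defects`).
#' @export
generate_scene <- function(params, config = goat_config()) {
  stopifnot(inherits(params, "scene_params"))
  cfg <- config
  nr <- cfg$frame$size[1]; nc <- cfg$frame$size[2]
  ppcm <- params$camera$pixels_per_cm %||% cfg$frame$pixels_per_cm
  ground_row <- round(cfg$scene$ground_row_frac * nr)
  center_col <- round(nc / 2)
  if (params$hw * ppcm > ground_row - 10 ||
      (params$bl * 1.3 + cfg$sign$width_cm + 15) * ppcm > nc) {
    stop("goat does not fit in the frame at this scale", call. = FALSE)
  }
  with_seed(params$seed, {
    # background: backdrop above, ground tarp below the fold line
    tarp_top <- round(cfg$scene$tarp_top_frac * nr)
    img <- array(0, c(nr, nc, 3))
    for (ch in 1:3) {
      pl <- matrix(cfg$scene$backdrop_rgb[ch], nr, nc)
      pl[tarp_top:nr, ] <- cfg$scene$tarp_rgb[ch]
      img[, , ch] <- pl
    }

    has_sign <- params$pose %in% c("sign", "rear")
    xoff <- if (has_sign) -30 else 0

    if (params$pose == "rear") {
      g <- rear_goat_mask(params, xoff, ground_row, center_col, ppcm, nr, nc)
      geom <- NULL
    } else {
      g <- side_goat_mask(params, xoff, ground_row, center_col, ppcm, nr, nc)
      geom <- g
    }
    gmask <- matrix(FALSE, nr, nc)
    gmask[g$rw, g$cl] <- g$mask

    # coat: columns split at mask-pixel column quantiles for patched coats
    coat_label <- matrix(0L, nr, nc)
    cols_of <- which(gmask, arr.ind = TRUE)
    ncoat <- length(params$coat_colors)
    if (params$pattern == "patched" && ncoat > 1) {
      qs <- cumsum(params$pattern_fracs)
      brk <- stats::quantile(cols_of[, 2], probs = qs[-length(qs)], type = 1)
      lab <- findInterval(cols_of[, 2], c(-Inf, brk, Inf))
    } else {
      lab <- rep(1L, nrow(cols_of))
    }
    coat_label[cols_of] <- lab
    true_fracs <- as.vector(table(factor(lab, levels = seq_len(ncoat)))) / length(lab)

    # calibration sign in the animal's plane, ahead of the head
    sign_corners <- NULL
    if (has_sign) {
      front_cm <- if (params$pose == "rear") xoff + params$chest_width / 2 + 6 else g$span_cm[2]
      skew <- if ("skewed_sign" %in% params$defects) 10 else 0
      sg <- sign_geometry(cfg, ppcm, front_cm + 12,
                          params$hw - params$chest_depth / 2, skew)
      sr <- render_sign(img, sg, cfg, ground_row, center_col, ppcm)
      img <- sr$img
      sign_corners <- sr$corners
    }

    # goat painted last: always on top
    for (k in seq_len(ncoat)) {
      sel <- coat_label == k
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[sel] <- params$coat_colors[[k]][ch]
        img[, , ch] <- pl
      }
    }

    inventory <- list()
    needs_grid <- length(params$defects) > 0
    if (needs_grid) {
      Rm <- matrix(seq_len(nr), nr, nc)
      Cm <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      tarp_rows <- Rm >= tarp_top
    }

    if ("dirty_tarp" %in% params$defects) {
      # mud patches on a jittered grid: large enough to wreck the blue
      # coverage, separated so no patch chains into a subject-sized blob
      cell_r <- floor((nr - tarp_top) / 3); cell_c <- floor(nc / 5)
      spl_all <- matrix(FALSE, nr, nc)
      n_spl <- 0L
      for (gr_i in 0:2) for (gc_i in 0:4) {
        rr <- tarp_top + (gr_i + 0.5) * cell_r + runif(1, -2, 2)
        cc <- (gc_i + 0.5) * cell_c + runif(1, -2, 2)
        rx <- 0.48 * cell_c; ryy <- 0.47 * cell_r
        spl_all <- spl_all | (((Cm - cc) / rx)^2 + ((Rm - rr) / ryy)^2 <= 1)
        n_spl <- n_spl + 1L
      }
      # the animal stands on the clean spots: keep a blue margin around the
      # silhouette so mud never fuses with the subject
      spl_all <- spl_all & tarp_rows & !dilate_mask(gmask, 6L)
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[spl_all] <- cfg$scene$dirt_rgb[ch]; img[, , ch] <- pl
      }
      inventory$dirty_tarp <- list(n = n_spl, dirt_px = sum(spl_all))
    }

    if ("missing_ground_tarp" %in% params$defects) {
      sel <- tarp_rows & !gmask
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[sel] <- cfg$scene$dirt_rgb[ch]; img[, , ch] <- pl
      }
      inventory$missing_ground_tarp <- list(tarp_top = tarp_top)
    }

    if ("rocks" %in% params$defects) {
      rocks_top <- ground_row - round(0.08 * nr)
      # feet hidden behind the rocks: visible goat stops above them
      cut <- gmask & Rm >= rocks_top
      gmask[cut] <- FALSE
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[cut] <- ifelse(Rm[cut] >= tarp_top,
                          cfg$scene$tarp_rgb[ch], cfg$scene$backdrop_rgb[ch])
        img[, , ch] <- pl
      }
      ctr <- center_col + xoff * ppcm
      rock_all <- matrix(FALSE, nr, nc)
      for (i in 1:4) {
        cc <- ctr + (i - 2.5) * 90 + runif(1, -15, 15)
        rr <- ground_row + runif(1, -5, 5)
        rock_all <- rock_all |
          (((Cm - cc) / runif(1, 35, 55))^2 + ((Rm - rr) / runif(1, 18, 28))^2 <= 1)
      }
      rock_all <- rock_all & Rm >= rocks_top + 3 & !gmask
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[rock_all] <- cfg$scene$rock_rgb[ch]; img[, , ch] <- pl
      }
      inventory$rocks <- list(rocks_top = rocks_top)
    }

    if ("handler_occluder" %in% params$defects) {
      cmin <- min(which(gmask, arr.ind = TRUE)[, 2])
      occ_col <- cmin - 20L - 30L
      occ <- Cm >= occ_col & Cm < occ_col + 30L &
             Rm >= ground_row - 300L & Rm < ground_row
      occ_rgb <- if (params$occluder_style == "blue") c(60, 100, 200) else cfg$scene$skin_rgb
      for (ch in 1:3) {
        pl <- img[, , ch]; pl[occ] <- occ_rgb[ch]; img[, , ch] <- pl
      }
      inventory$handler_occluder <- list(style = params$occluder_style, col = occ_col)
    }

    gain <- 1
    if ("lighting_shift" %in% params$defects) {
      gain <- params$lighting_gain %||% runif(1, 0.7, 1.3)
      img <- clamp(img * gain)
      inventory$lighting_shift <- list(gain = gain)
    }

    img <- clamp(round(img))

    measures <- body_measures(
      HW = if (params$pose == "rear") NA_real_ else params$hw,
      BL = if (params$pose == "rear") NA_real_ else params$bl,
      chest_depth = if (params$pose == "rear") NA_real_ else params$chest_depth,
      chest_width = if (params$pose == "rear") params$chest_width else NA_real_,
      CG = chest_girth(params$chest_depth, params$chest_width)
    )

    truth <- list(
      mask = gmask,
      scale = 1 / ppcm,
      ground_row = ground_row,
      withers = if (!is.null(geom)) c(row = ground_row - round(geom$withers_cm[2] * ppcm),
                                      col = center_col + round(geom$withers_cm[1] * ppcm)) else NULL,
      shoulder = if (!is.null(geom)) c(row = ground_row - round(geom$shoulder_cm[2] * ppcm),
                                       col = center_col + round(geom$shoulder_cm[1] * ppcm)) else NULL,
      pin = if (!is.null(geom)) c(row = ground_row - round(geom$pin_cm[2] * ppcm),
                                  col = center_col + round(geom$pin_cm[1] * ppcm)) else NULL,
      sign_corners = sign_corners,
      measures = measures,
      coat_fracs = true_fracs,
      coat_colors = params$coat_colors,
      lighting_gain = gain,
      defects = inventory
    )
    rec <- image_record(img, pose = if (params$pose == "rear") "rear"
                        else if (params$pose == "sign") "sign" else "side",
                        sample_id = sprintf("synth-%06d", params$seed))
    list(image = rec, truth = truth)
  })
}

#' Generate a synthetic FAMACHA eye close-up
#'
#' Renders fur, eyelid skin, a dark eyeball and an exposed conjunctiva
#' region whose color is the requested category's reference plus bounded
#' Gaussian noise.
#'
#' @param category integer FAMACHA category 1 (healthy red) to 5 (pale).
#' @param reference_colors 5 x 3 matrix of reference RGB rows; defaults to
#'   the configured ramp.
#' @param seed integer seed.
#' @param noise_sd per-channel noise sd (channel units); default from config.
#' @param config a [goat_config()].
#' @return list `image` (goat_image, pose `"eye"`), `truth` (conjunctiva
#'   mask, category, reference color).
#' @export
generate_eye_scene <- function(category, reference_colors = NULL, seed = 1L,
                               noise_sd = NULL, config = goat_config()) {
  if (!(length(category) == 1 && category %in% 1:5)) {
    stop("category must be an integer in 1..5", call. = FALSE)
  }
  cfg <- config
  refs <- reference_colors %||% cfg$famacha$refs
  sd <- noise_sd %||% cfg$famacha$noise_sd
  nr <- cfg$frame$eye_size[1]; nc <- cfg$frame$eye_size[2]
  with_seed(seed, {
    R <- row(matrix(0, nr, nc)); C <- col(matrix(0, nr, nc))
    img <- array(0, c(nr, nc, 3))
    fur <- c(120, 105, 95); lid <- c(145, 135, 120); ball <- c(60, 45, 40)
    for (ch in 1:3) img[, , ch] <- fur[ch]
    lid_m <- ((R - nr * 0.45) / (nr * 0.38))^2 + ((C - nc / 2) / (nc * 0.40))^2 <= 1
    ball_m <- ((R - nr * 0.38) / (nr * 0.17))^2 + ((C - nc / 2) / (nc * 0.30))^2 <= 1
    conj <- ((R - nr * 0.62) / (nr * 0.13))^2 + ((C - nc / 2) / (nc * 0.22))^2 <= 1
    ball_m <- ball_m & !conj
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[lid_m] <- lid[ch]
      pl[ball_m] <- ball[ch]
      base <- refs[category, ch]
      n <- sum(conj)
      pl[conj] <- clamp(round(base + if (sd > 0) rnorm(n, 0, sd) else 0))
      img[, , ch] <- pl
    }
    rec <- image_record(img, "eye", sprintf("synth-eye-%d-%d", category, seed))
    list(image = rec,
         truth = list(category = category, conj_mask = conj,
                      reference = refs[category, ], noise_sd = sd))
  })
}

#' Generate a synthetic teeth close-up
#'
#' Renders a lower-incisor row inside a dark mouth: `n_permanent_pairs`
#' pairs of large (permanent) incisors centered, remaining positions filled
#' with small deciduous teeth (4 pairs = 8 positions total).
#'
#' @param n_permanent_pairs integer 0..4.
#' @param seed integer seed.
#' @param config a [goat_config()].
#' @return list `image` (goat_image, pose `"teeth"`), `truth` (pair count,
#'   per-tooth boxes, permanent-pixel area).
#' @export
generate_teeth_scene <- function(n_permanent_pairs, seed = 1L,
                                 config = goat_config()) {
  if (!(length(n_permanent_pairs) == 1 && n_permanent_pairs %in% 0:4)) {
    stop("n_permanent_pairs must be an integer in 0..4", call. = FALSE)
  }
  cfg <- config
  nr <- cfg$frame$teeth_size[1]; nc <- cfg$frame$teeth_size[2]
  with_seed(seed, {
    R <- row(matrix(0, nr, nc)); C <- col(matrix(0, nr, nc))
    img <- array(0, c(nr, nc, 3))
    mouth <- c(45, 28, 30); gumc <- c(150, 85, 90); tooth <- c(238, 233, 224)
    for (ch in 1:3) img[, , ch] <- mouth[ch]
    gum <- R >= nr * 0.55 & R <= nr * 0.80
    for (ch in 1:3) { pl <- img[, , ch]; pl[gum] <- gumc[ch]; img[, , ch] <- pl }
    centers <- nc / 2 + (c(-4, -3, -2, -1, 1, 2, 3, 4) - sign(c(-4, -3, -2, -1, 1, 2, 3, 4)) * 0.5) * 46
    is_perm <- abs(c(-4, -3, -2, -1, 1, 2, 3, 4)) <= n_permanent_pairs
    boxes <- list(); perm_area <- 0L
    base_row <- nr * 0.62
    for (i in seq_along(centers)) {
      if (is_perm[i]) { w <- 34; h <- 60 } else { w <- 18; h <- 28 }
      tm <- C >= centers[i] - w / 2 & C < centers[i] + w / 2 &
            R >= base_row - h & R < base_row
      for (ch in 1:3) { pl <- img[, , ch]; pl[tm] <- tooth[ch]; img[, , ch] <- pl }
      boxes[[i]] <- list(center = centers[i], permanent = is_perm[i], area = sum(tm))
      if (is_perm[i]) perm_area <- perm_area + sum(tm)
    }
    rec <- image_record(img, "teeth", sprintf("synth-teeth-%d-%d", n_permanent_pairs, seed))
    list(image = rec,
         truth = list(n_permanent_pairs = n_permanent_pairs, teeth = boxes,
                      permanent_area_px = perm_area))
  })
}
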