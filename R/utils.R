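# Low-level raster helpers shared across modules.
# Images are numeric arrays [rows, cols, 3] in [0, 255]; masks are logical
# matrices [rows, cols]. EBImage stores images transposed (x = col first),
# so every EBImage call goes through t().

clamp <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

assert_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L ||
      dim(img)[1] < 1L || dim(img)[2] < 1L) {
    stop("image must be a non-empty [rows, cols, 3] array", call. = FALSE)
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop("image channel values must lie in [0, 255]", call. = FALSE)
  }
  invisible(img)
}

# 8-connected labeling. EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally with a union-find pass over the (small) label graph.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(t(mask * 1))
  lab <- t(EBImage::imageData(lab))
  n <- max(lab)
  if (n < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal pairs
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

component_stats <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(data.frame(label = integer(), area = integer(),
                                 crow = double(), ccol = double(),
                                 rmin = integer(), rmax = integer(),
                                 cmin = integer(), cmax = integer()))
  idx <- which(lab > 0)
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  data.frame(
    label = seq_len(n),
    area = as.integer(tabulate(l, n)),
    crow = vapply(split(r, l), mean, 0)[as.character(seq_len(n))],
    ccol = vapply(split(cc, l), mean, 0)[as.character(seq_len(n))],
    rmin = vapply(split(r, l), min, 0L)[as.character(seq_len(n))],
    rmax = vapply(split(r, l), max, 0L)[as.character(seq_len(n))],
    cmin = vapply(split(cc, l), min, 0L)[as.character(seq_len(n))],
    cmax = vapply(split(cc, l), max, 0L)[as.character(seq_len(n))]
  )
}

fill_holes <- function(mask) {
  f <- EBImage::fillHull(t(mask * 1))
  t(EBImage::imageData(f)) > 0
}

# interior boundary: mask pixels with a 4-neighbour outside the mask
mask_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
        pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  core & !nb
}

dilate_mask <- function(mask, px) {
  if (px <= 0) return(mask)
  k <- EBImage::makeBrush(2L * px + 1L, shape = "disc")
  t(EBImage::imageData(EBImage::dilate(t(mask * 1), k))) > 0
}

erode_mask <- function(mask, px) {
  if (px <= 0) return(mask)
  k <- EBImage::makeBrush(2L * px + 1L, shape = "disc")
  t(EBImage::imageData(EBImage::erode(t(mask * 1), k))) > 0
}

# Euclidean distance to the nearest FALSE pixel (0 on background)
mask_distmap <- function(mask) {
  t(EBImage::imageData(EBImage::distmap(t(mask * 1))))
}

# hue (deg), saturation, value for an image array; returns list of matrices
image_hsv <- function(img) {
  d <- dim(img)
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# integer pixel chain between two (row, col) points (Bresenham-style via
# dense interpolation; duplicates removed, order preserved)
segment_pixels <- function(p1, p2) {
  n <- max(abs(p2 - p1)) + 1L
  r <- round(seq(p1[1], p2[1], length.out = n))
  cc <- round(seq(p1[2], p2[2], length.out = n))
  keep <- !duplicated(cbind(r, cc))
  cbind(row = r[keep], col = cc[keep])
}

# which pixels of (rows, cols) lie inside the convex polygon `corners`
# (k x 2, (row, col), ordered either way). Half-plane test, vectorized.
in_convex_poly <- function(rows, cols, corners) {
  k <- nrow(corners)
  allpos <- rep(TRUE, length(rows))
  allneg <- rep(TRUE, length(rows))
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    er <- corners[j, 1] - corners[i, 1]
    ec <- corners[j, 2] - corners[i, 2]
    cr <- (rows - corners[i, 1]) * ec - (cols - corners[i, 2]) * er
    allpos <- allpos & cr >= 0
    allneg <- allneg & cr <= 0
  }
  allpos | allneg
}

rgb_hex <- function(v) grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255)

# CIELAB conversion for perceptual color distances (rows = colors)
rgb_to_lab <- function(m) {
  grDevices::convertColor(m / 255, from = "sRGB", to = "Lab")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
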