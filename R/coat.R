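# coat: calibrated coat color clusters and pattern summary from the
# unobscured "naked"/side view.

#' Coat color and pattern summary
#'
#' Clusters the color-corrected silhouette pixels into at most `K` groups
#' (k-means, fixed seed, 10 restarts; `K` shrinks to the number of distinct
#' colors when smaller). Clusters holding less than the merge fraction of
#' pixels are merged into their nearest remaining cluster. The coat is
#' `"solid"` when the top cluster holds at least 90 percent of pixels,
#' otherwise `"patched"`; the pattern map is the per-pixel cluster label
#' grid down-sampled by the configured factor (majority label per block).
#'
#' @param image `goat_image` (side pose) or array.
#' @param mask `goat_mask` or logical matrix of the silhouette.
#' @param transform a `color_transform` for calibration.
#' @param K maximum number of clusters.
#' @param config a [goat_config()].
#' @return object of class `coat_summary`: `clusters` (matrix with columns
#'   `R`, `G`, `B`, `fraction`, ordered by descending fraction),
#'   `pattern_class`, `pattern_map` (down-sampled label matrix, 0 outside
#'   the mask).
#' @export
coat_colors <- function(image, mask, transform = identity_transform(),
                        K = goat_config()$coat$K, config = goat_config()) {
  img <- if (inherits(image, "goat_image")) image$pixels else image
  m <- if (inherits(mask, "goat_mask")) mask$mask else mask
  stopifnot(all(dim(m) == dim(img)[1:2]))
  cc <- config$coat
  if (sum(m) < cc$min_area_px) stop("insufficient coat area", call. = FALSE)
  corrected <- apply_color_transform(img, transform)
  idx <- which(m)
  nrp <- nrow(m)
  px <- cbind(corrected[, , 1][idx], corrected[, , 2][idx], corrected[, , 3][idx])
  distinct <- unique(round(px))
  k_eff <- min(K, nrow(distinct))
  if (k_eff == 1L) {
    centers <- matrix(colMeans(px), 1)
    assign <- rep(1L, nrow(px))
  } else {
    km <- with_seed(cc$seed, stats::kmeans(px, centers = k_eff, nstart = 10,
                                           iter.max = 50))
    centers <- km$centers
    assign <- km$cluster
  }
  fr <- tabulate(assign, nrow(centers)) / length(assign)
  # merge small clusters into the nearest remaining centroid
  while (any(fr < cc$merge_frac) && length(fr) > 1L) {
    i <- which.min(fr)
    keep <- setdiff(seq_along(fr), i)
    d2 <- rowSums((centers[keep, , drop = FALSE] -
                     matrix(centers[i, ], length(keep), 3, byrow = TRUE))^2)
    j <- keep[which.min(d2)]
    assign[assign == i] <- j
    remap <- match(seq_along(fr), keep)   # NA for dropped
    assign <- remap[assign]
    centers <- centers[keep, , drop = FALSE]
    fr <- tabulate(assign, nrow(centers)) / length(assign)
    for (g in seq_len(nrow(centers))) {
      centers[g, ] <- colMeans(px[assign == g, , drop = FALSE])
    }
  }
  o <- order(-fr)
  centers <- centers[o, , drop = FALSE]
  fr <- fr[o]
  assign <- match(assign, o)
  clusters <- cbind(R = centers[, 1], G = centers[, 2], B = centers[, 3],
                    fraction = fr)
  pattern_class <- if (fr[1] >= cc$solid_frac) "solid" else "patched"

  lab_full <- matrix(0L, nrow(m), ncol(m))
  lab_full[idx] <- assign
  ds <- cc$downsample
  nbr <- ceiling(nrow(m) / ds); nbc <- ceiling(ncol(m) / ds)
  pattern_map <- matrix(0L, nbr, nbc)
  br <- (seq_len(nrow(m)) - 1L) %/% ds + 1L
  bc <- (seq_len(ncol(m)) - 1L) %/% ds + 1L
  pos <- which(lab_full > 0L, arr.ind = TRUE)
  if (nrow(pos) > 0L) {
    key <- paste(br[pos[, 1]], bc[pos[, 2]])
    val <- lab_full[pos]
    maj <- vapply(split(val, key), function(v) {
      as.integer(names(sort(table(v), decreasing = TRUE))[1])
    }, 0L)
    kk <- do.call(rbind, strsplit(names(maj), " "))
    pattern_map[cbind(as.integer(kk[, 1]), as.integer(kk[, 2]))] <- maj
  }
  structure(list(clusters = clusters, pattern_class = pattern_class,
                 pattern_map = pattern_map),
            class = "coat_summary")
}

#' @export
print.coat_summary <- function(x, ...) {
  cat(sprintf("coat: %s, %d cluster(s)\n", x$pattern_class, nrow(x$clusters)))
  for (i in seq_len(nrow(x$clusters))) {
    cat(sprintf("  %s  %.1f%%\n", rgb_hex(x$clusters[i, 1:3]),
                100 * x$clusters[i, "fraction"]))
  }
  invisible(x)
}

#' Run-length encode a pattern map
#'
#' Row-major run-length encoding of the down-sampled coat pattern labels,
#' exportable as csv.
#'
#' @param pattern_map integer label matrix from [coat_colors()].
#' @return data.frame with columns `row`, `start_col`, `length`, `label`.
#' @export
pattern_rle <- function(pattern_map) {
  out <- list()
  for (r in seq_len(nrow(pattern_map))) {
    rl <- rle(pattern_map[r, ])
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values > 0L
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(row = r, start_col = starts[keep],
                                            length = rl$lengths[keep],
                                            label = rl$values[keep])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(row = integer(), start_col = integer(),
                      length = integer(), label = integer()))
  }
  do.call(rbind, out)
}
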