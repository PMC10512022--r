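# Minimal EXIF (APP1/TIFF) support: just enough to embed and recover GPS
# position, capture time and camera model in JPEG files. Metadata is never
# fabricated: fields absent from the file come back NULL.

u16 <- function(x, endian) writeBin(as.integer(x), raw(), size = 2, endian = endian)
u32 <- function(x, endian) writeBin(as.integer(x), raw(), size = 4, endian = endian)

read_u16 <- function(raw, off, endian) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, signed = FALSE, endian = endian)
}
read_u32 <- function(raw, off, endian) {
  v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
  if (v < 0) v <- v + 2^32
  v
}

rational <- function(num, den, endian) c(u32(num, endian), u32(den, endian))

deg_to_dms_rationals <- function(deg, endian) {
  a <- abs(deg)
  d <- floor(a)
  m <- floor((a - d) * 60)
  s <- round(((a - d) * 60 - m) * 60 * 10000)
  c(rational(d, 1, endian), rational(m, 1, endian), rational(s, 10000, endian))
}

# Build the APP1 payload for the supported fields (little-endian TIFF).
build_exif_app1 <- function(gps = NULL, timestamp = NULL, camera_model = NULL) {
  en <- "little"
  ifd0 <- list()   # list of list(tag, type, count, value_raw)
  data_blobs <- list()

  add_ascii <- function(tag, text) {
    bytes <- c(charToRaw(text), as.raw(0))
    list(tag = tag, type = 2L, count = length(bytes), data = bytes)
  }
  if (!is.null(camera_model)) ifd0 <- c(ifd0, list(add_ascii(0x0110, camera_model)))
  if (!is.null(timestamp)) {
    dt <- gsub("-", ":", sub("T", " ", timestamp))
    ifd0 <- c(ifd0, list(add_ascii(0x0132, dt)))
  }
  has_gps <- !is.null(gps)
  n0 <- length(ifd0) + has_gps
  if (n0 == 0L) return(NULL)

  # IFD0 block: count + entries + next-offset
  ifd0_off <- 8L
  ifd0_size <- 2L + 12L * n0 + 4L
  data_off <- ifd0_off + ifd0_size

  entries <- raw()
  data_area <- raw()
  put_entry <- function(tag, type, count, payload) {
    e <- c(u16(tag, en), u16(type, en), u32(count, en))
    if (length(payload) <= 4L) {
      e <- c(e, payload, raw(4L - length(payload)))
    } else {
      e <- c(e, u32(data_off + length(data_area), en))
      data_area <<- c(data_area, payload)
    }
    entries <<- c(entries, e)
  }
  for (ent in ifd0) put_entry(ent$tag, ent$type, ent$count, ent$data)

  if (has_gps) {
    # assemble the GPS IFD first into a standalone blob placed after data_area
    gps_entries <- raw(); gps_data <- raw()
    n_gps <- 6L
    # offsets inside the GPS blob are unknown until we fix its position;
    # build with placeholder then patch: instead compute gps_off now.
    gps_off <- data_off + length(data_area) +
      if (!is.null(camera_model) || !is.null(timestamp)) 0L else 0L
    # reserve: payload for the pointer entry
    put_entry(0x8825, 4L, 1L, u32(0, en))  # patched below
    gps_off <- data_off + length(data_area)
    # patch pointer value (last entry's value field = last 4 bytes)
    entries[(length(entries) - 3L):length(entries)] <- u32(gps_off, en)

    gps_ifd_size <- 2L + 12L * n_gps + 4L
    gdata_off <- gps_off + gps_ifd_size
    gput <- function(tag, type, count, payload) {
      e <- c(u16(tag, en), u16(type, en), u32(count, en))
      if (length(payload) <= 4L) {
        e <- c(e, payload, raw(4L - length(payload)))
      } else {
        e <- c(e, u32(gdata_off + length(gps_data), en))
        gps_data <<- c(gps_data, payload)
      }
      gps_entries <<- c(gps_entries, e)
    }
    lat_ref <- if (gps[1] >= 0) "N" else "S"
    lon_ref <- if (gps[2] >= 0) "E" else "W"
    alt <- if (length(gps) >= 3 && !is.na(gps[3])) gps[3] else 0
    gput(0x0001, 2L, 2L, c(charToRaw(lat_ref), as.raw(0)))
    gput(0x0002, 5L, 3L, deg_to_dms_rationals(gps[1], en))
    gput(0x0003, 2L, 2L, c(charToRaw(lon_ref), as.raw(0)))
    gput(0x0004, 5L, 3L, deg_to_dms_rationals(gps[2], en))
    gput(0x0005, 1L, 1L, as.raw(if (alt < 0) 1L else 0L))
    gput(0x0006, 5L, 1L, rational(round(abs(alt) * 100), 100, en))
    gps_blob <- c(u16(n_gps, en), gps_entries, u32(0, en), gps_data)
    data_area <- c(data_area, gps_blob)
  }

  tiff <- c(charToRaw("II"), u16(42L, en), u32(ifd0_off, en),
            u16(n0, en), entries, u32(0L, en), data_area)
  payload <- c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
  seg_len <- length(payload) + 2L
  c(as.raw(c(0xFF, 0xE1)), as.raw(seg_len %/% 256L), as.raw(seg_len %% 256L), payload)
}

#' Write a JPEG with embedded EXIF metadata
#'
#' Encodes the pixel array as JPEG and inserts an APP1 EXIF segment holding
#' the GPS position (decimal degrees, altitude meters), ISO-8601 timestamp
#' and camera model. Used by the synthetic-scene tooling so the metadata
#' reader can be validated by round-trip.
#'
#' @param img `[rows, cols, 3]` array in `[0, 255]`.
#' @param path output file path.
#' @param gps optional numeric `c(lat, lon, alt)`.
#' @param timestamp optional ISO-8601 text, e.g. `"2024-05-01T09:30:00"`.
#' @param camera_model optional text.
#' @param quality JPEG quality in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_jpeg_exif <- function(img, path, gps = NULL, timestamp = NULL,
                            camera_model = NULL, quality = 0.95) {
  assert_image(img)
  tmp <- tempfile(fileext = ".jpg")
  on.exit(unlink(tmp), add = TRUE)
  jpeg::writeJPEG(img / 255, tmp, quality = quality)
  bytes <- readBin(tmp, "raw", file.info(tmp)$size)
  app1 <- build_exif_app1(gps, timestamp, camera_model)
  if (is.null(app1)) {
    writeBin(bytes, path)
  } else {
    stopifnot(bytes[1] == as.raw(0xFF), bytes[2] == as.raw(0xD8))
    writeBin(c(bytes[1:2], app1, bytes[-(1:2)]), path)
  }
  invisible(path)
}

parse_ifd <- function(tiff, off, endian) {
  n <- read_u16(tiff, off, endian)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    e_off <- off + 2L + (i - 1L) * 12L
    tag <- read_u16(tiff, e_off, endian)
    type <- read_u16(tiff, e_off + 2L, endian)
    count <- read_u32(tiff, e_off + 4L, endian)
    type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)[type]
    nbytes <- type_size * count
    val_off <- if (nbytes <= 4L) e_off + 8L else read_u32(tiff, e_off + 8L, endian)
    entries[[i]] <- list(tag = tag, type = type, count = count, off = val_off)
  }
  entries
}

ifd_ascii <- function(tiff, ent) {
  bytes <- tiff[(ent$off + 1L):(ent$off + ent$count)]
  rawToChar(bytes[bytes != as.raw(0)])
}

ifd_rationals <- function(tiff, ent, endian) {
  vapply(seq_len(ent$count), function(i) {
    o <- ent$off + (i - 1L) * 8L
    num <- read_u32(tiff, o, endian)
    den <- read_u32(tiff, o + 4L, endian)
    if (den == 0) NA_real_ else num / den
  }, 0)
}

#' Read EXIF metadata from a JPEG file
#'
#' Parses the APP1 EXIF segment (both byte orders) and extracts the GPS
#' position in decimal degrees with altitude in meters, the capture
#' timestamp as ISO-8601 text, and the camera model. Fields absent from the
#' file are returned as `NULL` — never invented.
#'
#' @param path JPEG file path.
#' @return list with elements `gps` (numeric `c(lat, lon, alt)` or `NULL`),
#'   `timestamp`, `camera_model`.
#' @export
read_exif <- function(path) {
  out <- list(gps = NULL, timestamp = NULL, camera_model = NULL)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 4) return(out)
  bytes <- readBin(path, "raw", sz)
  if (bytes[1] != as.raw(0xFF) || bytes[2] != as.raw(0xD8)) return(out)
  pos <- 2L
  tiff <- NULL
  while (pos + 4L <= length(bytes)) {
    if (bytes[pos + 1L] != as.raw(0xFF)) break
    marker <- as.integer(bytes[pos + 2L])
    if (marker == 0xDA || marker == 0xD9) break  # image data / EOI
    seg_len <- as.integer(bytes[pos + 3L]) * 256L + as.integer(bytes[pos + 4L])
    if (marker == 0xE1 && seg_len > 8L &&
        rawToChar(bytes[(pos + 5L):(pos + 8L)]) == "Exif") {
      tiff <- bytes[(pos + 11L):(pos + 2L + seg_len)]
      break
    }
    pos <- pos + 2L + seg_len
  }
  if (is.null(tiff)) return(out)
  endian <- if (rawToChar(tiff[1:2]) == "II") "little" else "big"
  ifd0 <- parse_ifd(tiff, read_u32(tiff, 4L, endian), endian)
  gps_ptr <- NULL
  for (ent in ifd0) {
    if (ent$tag == 0x0110) out$camera_model <- ifd_ascii(tiff, ent)
    if (ent$tag == 0x0132) {
      dt <- ifd_ascii(tiff, ent)
      out$timestamp <- sub(" ", "T", sub("^(\\d{4}):(\\d{2}):(\\d{2})", "\\1-\\2-\\3", dt))
    }
    if (ent$tag == 0x8825) gps_ptr <- read_u32(tiff, ent$off, endian)
  }
  if (!is.null(gps_ptr)) {
    gifd <- parse_ifd(tiff, gps_ptr, endian)
    lat <- lon <- alt <- NA_real_
    lat_sgn <- lon_sgn <- alt_sgn <- 1
    for (ent in gifd) {
      if (ent$tag == 0x0001 && ifd_ascii(tiff, ent) == "S") lat_sgn <- -1
      if (ent$tag == 0x0003 && ifd_ascii(tiff, ent) == "W") lon_sgn <- -1
      if (ent$tag == 0x0002) {
        d <- ifd_rationals(tiff, ent, endian)
        lat <- d[1] + d[2] / 60 + d[3] / 3600
      }
      if (ent$tag == 0x0004) {
        d <- ifd_rationals(tiff, ent, endian)
        lon <- d[1] + d[2] / 60 + d[3] / 3600
      }
      if (ent$tag == 0x0005 && tiff[ent$off + 1L] == as.raw(1)) alt_sgn <- -1
      if (ent$tag == 0x0006) alt <- ifd_rationals(tiff, ent, endian)[1]
    }
    if (!is.na(lat) && !is.na(lon)) {
      out$gps <- c(lat = lat_sgn * lat, lon = lon_sgn * lon,
                   alt = if (is.na(alt)) NA_real_ else alt_sgn * alt)
    }
  }
  out
}
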