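# io_formats: image + metadata input, phenotype tables and labeled overlays.

POSES <- c("rear", "sign", "side", "eye", "teeth")

#' Load a photograph as an image record
#'
#' Decodes a JPEG or PNG file into a `[rows, cols, 3]` array in `[0, 255]`
#' and, for JPEG, extracts GPS position, timestamp and camera model from the
#' EXIF segment when present. Metadata absent from the file stays `NULL`.
#'
#' @param path image file (JPEG or PNG).
#' @param pose one of `"rear"`, `"sign"`, `"side"`, `"eye"`, `"teeth"`.
#' @param sample_id animal identifier text.
#' @return an object of class `goat_image` with fields `pixels`, `pose`,
#'   `sample_id`, `gps`, `timestamp`, `camera_model`, `source_path`.
#' @export
load_image <- function(path, pose, sample_id = "") {
  if (!pose %in% POSES) {
    stop("unknown pose label '", pose, "'; must be one of ",
         paste(POSES, collapse = ", "), call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  bytes <- readBin(path, "raw", n = 8)
  is_png <- length(bytes) >= 8 && identical(bytes[1:4], as.raw(c(0x89, 0x50, 0x4E, 0x47)))
  is_jpg <- length(bytes) >= 2 && identical(bytes[1:2], as.raw(c(0xFF, 0xD8)))
  px <- tryCatch({
    if (is_png) png::readPNG(path)
    else if (is_jpg) jpeg::readJPEG(path)
    else stop("not a JPEG or PNG")
  }, error = function(e) stop("cannot decode image '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px <- round(px * 255)
  meta <- if (is_jpg) read_exif(path) else list(gps = NULL, timestamp = NULL, camera_model = NULL)
  structure(list(pixels = px, pose = pose, sample_id = sample_id,
                 gps = meta$gps, timestamp = meta$timestamp,
                 camera_model = meta$camera_model, source_path = path),
            class = "goat_image")
}

#' Construct an image record from an in-memory array
#'
#' @param pixels `[rows, cols, 3]` array in `[0, 255]`.
#' @inheritParams load_image
#' @param gps,timestamp,camera_model optional metadata.
#' @return a `goat_image` object.
#' @export
image_record <- function(pixels, pose, sample_id = "", gps = NULL,
                         timestamp = NULL, camera_model = NULL) {
  assert_image(pixels)
  stopifnot(pose %in% POSES)
  structure(list(pixels = pixels, pose = pose, sample_id = sample_id,
                 gps = gps, timestamp = timestamp, camera_model = camera_model,
                 source_path = NA_character_),
            class = "goat_image")
}

#' @export
print.goat_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("goat_image: %s pose '%s' (%d x %d px)%s\n",
              x$sample_id, x$pose, d[1], d[2],
              if (!is.null(x$gps)) sprintf(" GPS %.4f, %.4f", x$gps[1], x$gps[2]) else ""))
  invisible(x)
}

PHENO_NUM_COLS <- c("HW", "BL", "chest_depth", "chest_width", "CG", "BW",
                    "famacha", "permanent_pairs",
                    "coat_frac1", "coat_frac2", "coat_frac3",
                    "gps_lat", "gps_lon", "gps_alt")
PHENO_CHR_COLS <- c("sample_id", "age_class", "coat_color1", "coat_color2",
                    "coat_color3", "pattern_class", "qc_flags", "timestamp",
                    "camera_model")
PHENO_COLS <- c("sample_id", "HW", "BL", "chest_depth", "chest_width", "CG",
                "BW", "famacha", "permanent_pairs", "age_class",
                "coat_color1", "coat_frac1", "coat_color2", "coat_frac2",
                "coat_color3", "coat_frac3", "pattern_class", "qc_flags",
                "gps_lat", "gps_lon", "gps_alt", "timestamp", "camera_model")

#' Flatten phenotype records into a table
#'
#' One row per animal; absent optional phenotypes become `NA` (serialized as
#' empty fields, never zero).
#'
#' @param records list of phenotype records as returned by [process_animal()].
#' @return data.frame with one row per record.
#' @export
phenotype_table <- function(records) {
  stopifnot(length(records) > 0)
  rows <- lapply(records, function(r) {
    m <- r$measures %||% list()
    coat <- r$coat
    cc <- rep(NA_character_, 3); cf <- rep(NA_real_, 3); pc <- NA_character_
    if (!is.null(coat)) {
      k <- min(3L, nrow(coat$clusters))
      for (i in seq_len(k)) {
        cc[i] <- rgb_hex(coat$clusters[i, c("R", "G", "B")])
        cf[i] <- coat$clusters[i, "fraction"]
      }
      pc <- coat$pattern_class
    }
    md <- r$metadata %||% list()
    data.frame(
      sample_id = r$sample_id,
      HW = m$HW %||% NA_real_, BL = m$BL %||% NA_real_,
      chest_depth = m$chest_depth %||% NA_real_,
      chest_width = m$chest_width %||% NA_real_,
      CG = m$CG %||% NA_real_, BW = m$BW %||% NA_real_,
      famacha = r$famacha %||% NA_real_,
      permanent_pairs = if (is.null(r$tooth)) NA_real_ else r$tooth$permanent_pairs,
      age_class = if (is.null(r$tooth)) NA_character_ else r$tooth$age_class,
      coat_color1 = cc[1], coat_frac1 = cf[1],
      coat_color2 = cc[2], coat_frac2 = cf[2],
      coat_color3 = cc[3], coat_frac3 = cf[3],
      pattern_class = pc,
      qc_flags = paste(r$qc_flags %||% character(), collapse = ";"),
      gps_lat = if (is.null(md$gps)) NA_real_ else unname(md$gps[1]),
      gps_lon = if (is.null(md$gps)) NA_real_ else unname(md$gps[2]),
      gps_alt = if (is.null(md$gps)) NA_real_ else unname(md$gps[3]),
      timestamp = md$timestamp %||% NA_character_,
      camera_model = md$camera_model %||% NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write phenotype records to csv, xlsx or xml
#'
#' One row (or `<animal>` element) per animal. Missing optional phenotypes
#' are serialized as empty fields, never zero. The csv dialect is RFC-4180
#' comma-separated with a header row.
#'
#' @param records list of phenotype records, or a data.frame already in
#'   [phenotype_table()] layout.
#' @param format one of `"csv"`, `"xlsx"`, `"xml"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, format = c("csv", "xlsx", "xml"), path) {
  format <- match.arg(format)
  df <- if (is.data.frame(records)) records else phenotype_table(records)
  stopifnot(nrow(df) > 0)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else if (format == "xlsx") {
    write_xlsx_minimal(df, path)
  } else {
    root <- xml2::xml_new_root("phenotypes")
    for (i in seq_len(nrow(df))) {
      an <- xml2::xml_add_child(root, "animal")
      for (nm in names(df)) {
        v <- df[[nm]][i]
        txt <- if (is.na(v)) "" else if (is.numeric(v)) format(v, digits = 15) else as.character(v)
        xml2::xml_add_child(an, nm, txt)
      }
    }
    xml2::write_xml(root, path)
  }
  invisible(path)
}

#' Read a phenotype table back from csv, xlsx or xml
#'
#' Inverse of [write_phenotypes()]; numeric columns are restored as numeric,
#' empty fields as `NA`.
#'
#' @inheritParams write_phenotypes
#' @param path file to read.
#' @return data.frame in [phenotype_table()] layout.
#' @export
read_phenotypes <- function(path, format = c("csv", "xlsx", "xml")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "")
  } else if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package")
    }
    df <- as.data.frame(readxl::read_excel(path, col_types = "text"),
                        stringsAsFactors = FALSE)
  } else {
    doc <- xml2::read_xml(path)
    animals <- xml2::xml_find_all(doc, "./animal")
    rows <- lapply(animals, function(a) {
      kids <- xml2::xml_children(a)
      vals <- xml2::xml_text(kids)
      names(vals) <- xml2::xml_name(kids)
      as.data.frame(as.list(vals), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df[df == ""] <- NA
  }
  for (nm in intersect(PHENO_NUM_COLS, names(df))) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in intersect(PHENO_CHR_COLS, names(df))) {
    df[[nm]] <- as.character(df[[nm]])
    df[[nm]][is.na(df[[nm]])] <- NA_character_
  }
  if ("qc_flags" %in% names(df)) df$qc_flags[is.na(df$qc_flags)] <- ""
  df
}

#' Write a labeled overlay image
#'
#' Draws measurement line segments, the calibration-sign quadrilateral and
#' an optional mask tint onto a copy of the source image and writes a
#' lossless PNG. Source pixels outside overlay strokes are unchanged.
#'
#' @param image a `goat_image` or `[rows, cols, 3]` array.
#' @param mask optional logical mask matching the image; tinted pixels are
#'   blended toward `mask_tint`.
#' @param annotations list with optional elements `segments` (list of
#'   `list(p1 = c(row, col), p2 = c(row, col), color = c(r, g, b))`) and
#'   `quad` (4 x 2 matrix of corners, drawn closed).
#' @param path output PNG path.
#' @param mask_tint RGB triplet for the mask overlay.
#' @return `path`, invisibly.
#' @export
write_labeled_image <- function(image, mask = NULL, annotations = list(),
                                path, mask_tint = c(255, 0, 255)) {
  img <- if (inherits(image, "goat_image")) image$pixels else image
  assert_image(img)
  out <- img
  if (!is.null(mask)) {
    m <- if (inherits(mask, "goat_mask")) mask$mask else mask
    if (!all(dim(m) == dim(img)[1:2])) stop("mask and image shapes differ", call. = FALSE)
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[m] <- 0.5 * pl[m] + 0.5 * mask_tint[ch]
      out[, , ch] <- pl
    }
  }
  draw_seg <- function(p1, p2, col) {
    px <- segment_pixels(round(p1), round(p2))
    keep <- px[, 1] >= 1 & px[, 1] <= dim(out)[1] & px[, 2] >= 1 & px[, 2] <= dim(out)[2]
    px <- px[keep, , drop = FALSE]
    for (ch in 1:3) out[cbind(px[, 1], px[, 2], ch)] <<- col[ch]
  }
  for (s in annotations$segments %||% list()) {
    draw_seg(s$p1, s$p2, s$color %||% c(255, 255, 0))
  }
  if (!is.null(annotations$quad)) {
    q <- annotations$quad
    for (i in 1:4) draw_seg(q[i, ], q[if (i == 4) 1 else i + 1, ], c(0, 255, 255))
  }
  png::writePNG(clamp(out) / 255, path)
  invisible(path)
}

#' Read a per-animal pose manifest
#'
#' The manifest is a csv with columns `sample_id`, `pose`, `path` plus any
#' free-text demographic columns (sex, birth date, owner, breed, location,
#' country). Each row points one pose image at one animal.
#'
#' @param path manifest csv.
#' @return data.frame; errors if poses are invalid or paths duplicated
#'   within an animal.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pose", "path")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("manifest is empty", call. = FALSE)
  bad <- setdiff(unique(df$pose), POSES)
  if (length(bad)) stop("manifest has unknown pose labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  dup <- stats::aggregate(path ~ sample_id, df, function(p) anyDuplicated(p) > 0)
  if (any(dup$path)) stop("duplicate image paths within an animal", call. = FALSE)
  df
}

#' Read a manual body-measure table
#'
#' Columns: `sample_id` plus any of `HW`, `BL`, `CG`, `PB`, `SB`, `BW`
#' (cm / kg). Used as the manual side of digital-vs-manual validation;
#' PB and SB are manual-only fields, never computed digitally.
#'
#' @param path csv file.
#' @return data.frame with numeric measure columns.
#' @export
read_manual_measures <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(df))
  for (nm in intersect(c("HW", "BL", "CG", "PB", "SB", "BW"), names(df))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}
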