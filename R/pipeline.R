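# pipeline_cli: per-animal orchestration from a pose manifest. Any
# single-stage failure is captured as a flag on the record, never a crash;
# phenotypes from other stages are unaffected.

stage_try <- function(flags_env, code, expr) {
  tryCatch(expr, error = function(e) {
    flags_env$flags <- c(flags_env$flags,
                         paste0(code, ":", gsub("[,;\n]", " ", conditionMessage(e))))
    NULL
  })
}

#' Process one animal's poses into a phenotype record
#'
#' Runs load, segmentation, calibration, morphometry, health scoring and
#' coat summarization for whichever poses are available. Body measures
#' need the sign and rear views; the eye, teeth and side views add
#' FAMACHA, tooth age and coat phenotypes. Missing poses yield absent
#' phenotypes plus a flag; a failing stage never blocks the others.
#'
#' @param manifest data.frame rows for one animal (columns `sample_id`,
#'   `pose`, `path`, optional demographics), or a named list mapping pose
#'   names to file paths with a `sample_id` entry.
#' @param config a [goat_config()].
#' @param images optional named list of pre-loaded `goat_image`s keyed by
#'   pose, bypassing disk I/O (used by the synthetic pipeline).
#' @return a `phenotype_record` list: `sample_id`, `measures`
#'   (`body_measures`), `famacha`, `tooth`, `coat`, `qc_flags`, `metadata`,
#'   `demographics`, plus intermediate `detections` for labeled output.
#' @export
process_animal <- function(manifest = NULL, config = goat_config(), images = NULL) {
  fe <- new.env(); fe$flags <- character()
  demo <- NULL
  sample_id <- ""
  if (is.null(images)) {
    if (is.data.frame(manifest)) {
      sample_id <- manifest$sample_id[1]
      demo <- manifest[1, setdiff(names(manifest), c("pose", "path")), drop = FALSE]
      images <- list()
      for (i in seq_len(nrow(manifest))) {
        p <- manifest$pose[i]
        im <- stage_try(fe, paste0("LOAD_FAILED_", toupper(p)),
                        load_image(manifest$path[i], p, sample_id))
        if (!is.null(im)) images[[p]] <- im
      }
    } else {
      sample_id <- manifest$sample_id %||% ""
      images <- list()
      for (p in intersect(names(manifest), POSES)) {
        im <- stage_try(fe, paste0("LOAD_FAILED_", toupper(p)),
                        load_image(manifest[[p]], p, sample_id))
        if (!is.null(im)) images[[p]] <- im
      }
    }
  } else {
    sample_id <- images[[1]]$sample_id %||% ""
  }
  if (length(images) == 0L) {
    stop("no images could be loaded for animal '", sample_id, "'", call. = FALSE)
  }
  for (p in setdiff(c("sign", "rear"), names(images))) {
    fe$flags <- c(fe$flags, paste0("MISSING_POSE_", toupper(p)))
  }

  cal <- NULL; transform <- identity_transform()
  detections <- list()
  if ("sign" %in% names(images)) {
    cal <- stage_try(fe, "SIGN_NOT_FOUND",
                     calibrate_from_sign(images$sign, config))
    if (!is.null(cal)) {
      transform <- cal$transform
      detections$sign <- cal$detection
    }
  }

  measures <- body_measures()
  seg_sign <- NULL
  if ("sign" %in% names(images) && !is.null(cal)) {
    seg_sign <- stage_try(fe, "SEGMENT_FAILED_SIGN", {
      bg <- classify_blue(images$sign, config$blue)
      mk <- isolate_roi(images$sign, bg, config$priors,
                        exclude = cal$detection$sign_mask)
      refine_edges(images$sign, mk, config$refine$window_px, config$refine$min_grad)
    })
    if (!is.null(seg_sign)) {
      fe$flags <- c(fe$flags, seg_sign$flags,
                    qc_scene(images$sign, seg_sign, config,
                             sign_mask = cal$detection$sign_mask))
      g <- stage_try(fe, "GROUND_FAILED", ground_row(seg_sign))
      hw <- stage_try(fe, "HW_FAILED",
                      height_at_withers(seg_sign, cal$scale, g, config$bands))
      bl <- stage_try(fe, "BL_FAILED",
                      body_length(seg_sign, cal$scale, g, config$bands))
      dp <- stage_try(fe, "DEPTH_FAILED",
                      chest_depth(seg_sign, cal$scale, g, config$bands))
      measures$HW <- hw$HW %||% NA_real_
      measures$BL <- bl$BL %||% NA_real_
      measures$chest_depth <- dp %||% NA_real_
      if (!is.null(hw)) {
        fe$flags <- c(fe$flags, hw$flags)
        detections$withers <- hw$withers
        detections$ground_row <- hw$ground_row
      }
      if (!is.null(bl)) detections$shoulder <- bl$shoulder
      if (!is.null(bl)) detections$pin <- bl$pin
    }
  }

  if ("rear" %in% names(images)) {
    rear_cal <- stage_try(fe, "REAR_SIGN_NOT_FOUND", calibrate_from_sign(images$rear, config))
    rear_scale <- if (!is.null(rear_cal)) rear_cal$scale else {
      if (!is.null(cal)) fe$flags <- c(fe$flags, "REAR_SCALE_FALLBACK")
      if (!is.null(cal)) cal$scale else NA_real_
    }
    if (!is.na(rear_scale)) {
      seg_rear <- stage_try(fe, "SEGMENT_FAILED_REAR", {
        bg <- classify_blue(images$rear, config$blue)
        pri <- config$priors
        pri$min_area_frac <- pri$rear_min_area_frac %||% pri$min_area_frac
        mk <- isolate_roi(images$rear, bg, pri,
                          exclude = if (!is.null(rear_cal)) rear_cal$detection$sign_mask)
        refine_edges(images$rear, mk, config$refine$window_px, config$refine$min_grad)
      })
      if (!is.null(seg_rear)) {
        cw <- stage_try(fe, "WIDTH_FAILED",
                        chest_width(seg_rear, rear_scale, config$bands))
        measures$chest_width <- cw %||% NA_real_
      }
    }
  }

  if (!is.na(measures$chest_depth) && !is.na(measures$chest_width)) {
    measures$CG <- chest_girth(measures$chest_depth, measures$chest_width)
  }
  bw <- predict_weight(measures, config$weight)
  measures$BW <- bw$BW
  fe$flags <- c(fe$flags, bw$flags)

  famacha <- NULL
  if ("eye" %in% names(images)) {
    fam <- stage_try(fe, "FAMACHA_FAILED",
                     famacha_score(images$eye, transform, config$famacha$refs, config))
    if (!is.null(fam)) famacha <- fam$category
  }
  tooth <- NULL
  if ("teeth" %in% names(images)) {
    tooth <- stage_try(fe, "TOOTH_FAILED",
                       tooth_age(images$teeth, config$teeth$age_map, config))
  }
  coat <- NULL
  if ("side" %in% names(images)) {
    coat <- stage_try(fe, "COAT_FAILED", {
      bg <- classify_blue(images$side, config$blue)
      mk <- isolate_roi(images$side, bg, config$priors)
      mk <- refine_edges(images$side, mk, config$refine$window_px, config$refine$min_grad)
      coat_colors(images$side, mk, transform, config$coat$K, config)
    })
  }

  meta <- NULL
  for (p in c("sign", "rear", "side", "eye", "teeth")) {
    if (p %in% names(images)) {
      im <- images[[p]]
      meta <- list(gps = im$gps, timestamp = im$timestamp,
                   camera_model = im$camera_model)
      if (!is.null(im$gps) || !is.null(im$timestamp)) break
    }
  }

  structure(list(sample_id = sample_id, measures = measures,
                 famacha = famacha, tooth = tooth, coat = coat,
                 qc_flags = unique(fe$flags), metadata = meta,
                 demographics = demo, detections = detections,
                 seg_sign = seg_sign),
            class = "phenotype_record")
}

#' @export
print.phenotype_record <- function(x, ...) {
  cat("phenotype record for", x$sample_id, "\n  ")
  print(x$measures)
  if (!is.null(x$famacha)) cat("  FAMACHA:", x$famacha, "\n")
  if (!is.null(x$tooth)) cat("  teeth:", x$tooth$permanent_pairs, "pairs ->",
                             x$tooth$age_class, "\n")
  if (!is.null(x$coat)) cat("  coat:", x$coat$pattern_class, "\n")
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}

#' Batch-process a pose manifest
#'
#' Processes every animal in the manifest in deterministic `sample_id`
#' order, writes the phenotype table, optional labeled sign-view images and
#' a per-stage log. Per-animal failures are logged and skipped, never
#' fatal.
#'
#' @param manifest manifest csv path or data.frame (see [read_manifest()]).
#' @param config a [goat_config()].
#' @param out_dir output directory (created if needed).
#' @param format phenotype table format: csv, xlsx or xml.
#' @param labeled_images write overlay PNGs for sign views.
#' @return invisible list: `table` (data.frame), `n_processed`,
#'   `n_flagged`, `n_failed`, `out_file`.
#' @export
run_batch <- function(manifest, config = goat_config(), out_dir,
                      format = c("csv", "xlsx", "xml"), labeled_images = FALSE) {
  format <- match.arg(format)
  mf <- if (is.data.frame(manifest)) manifest else read_manifest(manifest)
  if (nrow(mf) == 0) stop("empty manifest", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sort(unique(mf$sample_id))
  log_lines <- character()
  records <- list()
  n_failed <- 0L
  for (id in ids) {
    sub <- mf[mf$sample_id == id, , drop = FALSE]
    rec <- tryCatch(process_animal(sub, config), error = function(e) e)
    if (inherits(rec, "error")) {
      n_failed <- n_failed + 1L
      log_lines <- c(log_lines, sprintf("%s\tFAILED\t%s", id, conditionMessage(rec)))
      next
    }
    records[[length(records) + 1L]] <- rec
    log_lines <- c(log_lines, sprintf("%s\tOK\t%s", id,
                                      paste(rec$qc_flags, collapse = ";")))
    if (labeled_images && !is.null(rec$seg_sign)) {
      sgn <- sub$path[sub$pose == "sign"]
      if (length(sgn) == 1L) {
        img <- load_image(sgn, "sign", id)
        ann <- list()
        if (!is.null(rec$detections$withers) && !is.null(rec$detections$ground_row)) {
          wc <- rec$detections$withers
          ann$segments <- list(list(p1 = c(wc["row"], wc["col"]),
                                    p2 = c(rec$detections$ground_row, wc["col"]),
                                    color = c(255, 255, 0)))
        }
        if (!is.null(rec$detections$sign)) ann$quad <- rec$detections$sign$corners
        write_labeled_image(img, rec$seg_sign, ann,
                            file.path(out_dir, paste0(id, "_sign_labeled.png")))
      }
    }
  }
  if (length(records) == 0L) stop("no animal processed successfully", call. = FALSE)
  tab <- phenotype_table(records)
  tab <- tab[order(tab$sample_id), , drop = FALSE]
  out_file <- file.path(out_dir, paste0("phenotypes.", format))
  write_phenotypes(tab, format, out_file)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  n_flagged <- sum(vapply(records, function(r) length(r$qc_flags) > 0, TRUE))
  summary_line <- sprintf("processed %d, flagged %d, failed %d",
                          length(records), n_flagged, n_failed)
  log_lines <- c(log_lines, summary_line)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  message(summary_line)
  invisible(list(table = tab, n_processed = length(records),
                 n_flagged = n_flagged, n_failed = n_failed,
                 out_file = out_file))
}
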