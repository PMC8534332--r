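#' Read sequence metadata from a sidecar file
#'
#' The sidecar is a small structured-text file (YAML `key: value` pairs, or
#' JSON when the extension is `.json`) with fields `px_per_cm` (mandatory),
#' `fps` (default 38), `frame_step` (default 4) and optionally `axis_labels`.
#'
#' @param path path to the sidecar file.
#' @return a [sequence_meta()].
#' @export
read_sequence_meta <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else yaml::read_yaml(path)
  if (is.null(vals$px_per_cm))
    stopf("metadata file %s is missing the mandatory key 'px_per_cm'", path)
  sequence_meta(px_per_cm = vals$px_per_cm,
                fps = if (is.null(vals$fps)) 38 else vals$fps,
                frame_step = if (is.null(vals$frame_step)) 4L else vals$frame_step,
                axis_labels = vals$axis_labels)
}

#' Write sequence metadata to a sidecar file
#'
#' @param meta a [sequence_meta()].
#' @param path destination; format chosen by extension (`.json` for JSON,
#'   anything else YAML).
#' @return `path`, invisibly.
#' @export
write_sequence_meta <- function(meta, path) {
  stopifnot(inherits(meta, "sequence_meta"))
  vals <- list(px_per_cm = meta$px_per_cm, fps = meta$fps,
               frame_step = meta$frame_step)
  if (!is.null(meta$axis_labels)) vals$axis_labels <- as.list(meta$axis_labels)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = {
      fr <- tiff::readTIFF(path, all = TRUE)
      if (is.list(fr)) {
        if (length(fr) != 1L)
          stopf("%s is a multipage TIFF; pass the stack itself to read_mask_sequence", path)
        fr[[1]]
      } else fr
    },
    stopf("unsupported mask image format '%s' (%s)", ext, path)
  )
  binarize(img)
}

# parse a trailing integer out of a filename, NA when absent
trailing_index <- function(fname) {
  m <- regmatches(fname, regexpr("[0-9]+(?=\\.[A-Za-z]+$)", fname, perl = TRUE))
  if (length(m) == 0L) NA_integer_ else as.integer(m)
}

#' Read a mask sequence from disk
#'
#' `path` may be a directory of per-frame image files (PNG or single-page
#' TIFF, ordered by lexicographic file name) or a single multipage TIFF
#' stack. Source images may be 8-bit 0/255 exports or multi-channel; any
#' pixel value greater than zero maps to foreground (1). Frame indices are
#' taken from a trailing integer in each file name when every file carries
#' one (and they are strictly increasing in name order); otherwise frames are
#' numbered by position `0..n-1`.
#'
#' @param path directory of frame images or a multipage TIFF file.
#' @param meta_path path to the metadata sidecar (see [read_sequence_meta()]).
#' @return a [mask_sequence()].
#' @export
read_mask_sequence <- function(path, meta_path) {
  meta <- read_sequence_meta(meta_path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stopf("no mask images found in %s", path)
    mats <- lapply(files, read_one_image)
    idx <- vapply(basename(files), trailing_index, integer(1), USE.NAMES = FALSE)
    if (anyNA(idx) || any(diff(idx) <= 0)) idx <- seq_along(mats) - 1L
  } else if (file.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("tif", "tiff"))
      stopf("a single-file mask source must be a multipage TIFF (got .%s)", ext)
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    mats <- lapply(frames, binarize)
    idx <- seq_along(mats) - 1L
  } else {
    stopf("mask source not found: %s", path)
  }
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    off <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    stopf("inconsistent frame dimensions: frame %d is %dx%d, expected %dx%d",
          off, dims[1, off], dims[2, off], dims[1, 1], dims[2, 1])
  }
  frames <- Map(mask_frame, mats, idx)
  mask_sequence(frames, meta)
}

#' Write a mask sequence to disk
#'
#' Writes either a directory of per-frame PNG files named
#' `frame_<index>.png` (default; preserves frame indices) or a single
#' multipage TIFF stack (frame indices become positions `0..n-1`).
#'
#' @param seq a [mask_sequence()].
#' @param path destination directory (PNG) or `.tif` file (TIFF stack).
#' @param meta_path optional sidecar destination; written with
#'   [write_sequence_meta()] when given.
#' @param format `"png"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_mask_sequence <- function(seq, path, meta_path = NULL,
                                format = c("png", "tiff")) {
  stopifnot(inherits(seq, "mask_sequence"))
  format <- match.arg(format)
  if (format == "png") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (fr in seq$frames) {
      fn <- file.path(path, sprintf("frame_%06d.png", frame_index_of(fr)))
      png::writePNG(as_pixel_matrix(fr) * 1.0, fn)
    }
  } else {
    mats <- lapply(seq$frames, as_pixel_matrix)
    tiff::writeTIFF(lapply(mats, function(m) m * 1.0), path,
                    bits.per.sample = 8L)
  }
  if (!is.null(meta_path)) write_sequence_meta(seq$meta, meta_path)
  invisible(path)
}

metrics_columns <- c("frame_index", "time_s", "csa_px", "csa_cm2", "cx_px",
                     "cy_px", "cx_cm", "cy_cm", "perimeter_px", "perimeter_cm",
                     "circularity", "step_displacement_cm")

#' Write a per-frame morphology metrics table
#'
#' Writes one CSV row per frame with a header; invalid frames carry empty
#' (NA) metric fields. Values round-trip through [read_metrics_table()] to at
#' least 10 significant digits.
#'
#' @param records data frame of per-frame metrics as returned by
#'   [sequence_metrics()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stopf("records must be a non-empty data frame")
  miss <- setdiff(metrics_columns, names(records))
  if (length(miss)) stopf("records is missing columns: %s",
                          paste(miss, collapse = ", "))
  write.csv(records[, metrics_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-frame morphology metrics table
#'
#' @param path CSV written by [write_metrics_table()].
#' @return data frame with the metric columns plus a logical `valid` column
#'   (`FALSE` for frames whose metric fields are empty).
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) stopf("metrics table not found: %s", path)
  df <- read.csv(path)
  miss <- setdiff(metrics_columns, names(df))
  if (length(miss)) stopf("metrics table %s is missing columns: %s", path,
                          paste(miss, collapse = ", "))
  df <- df[, metrics_columns]
  df$valid <- !is.na(df$csa_px)
  df
}

#' Write instance-candidate sets
#'
#' Serializes one PNG mask per candidate,
#' `frame_<frame>_cand_<k>.png`, plus a score table `scores.csv` keyed by
#' `(frame_index, candidate_index)`. Frames with an empty candidate list
#' appear in the score table with candidate count 0 via a `frames.csv`
#' listing `(frame_index, n_candidates, h, w)`.
#'
#' @param cands list of [candidate_set()] objects.
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
write_candidate_sets <- function(cands, dir) {
  stopifnot(all(vapply(cands, inherits, logical(1), "candidate_set")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  frames <- data.frame(frame_index = integer(), n_candidates = integer(),
                       h = integer(), w = integer())
  for (cs in cands) {
    frames <- rbind(frames, data.frame(frame_index = cs$frame_index,
                                       n_candidates = length(cs$masks),
                                       h = cs$dim[1], w = cs$dim[2]))
    for (k in seq_along(cs$masks)) {
      fn <- sprintf("frame_%06d_cand_%03d.png", cs$frame_index, k)
      png::writePNG(cs$masks[[k]] * 1.0, file.path(dir, fn))
      rows[[length(rows) + 1L]] <- data.frame(frame_index = cs$frame_index,
                                              candidate_index = k,
                                              score = cs$scores[k])
    }
  }
  scores <- if (length(rows)) do.call(rbind, rows)
            else data.frame(frame_index = integer(), candidate_index = integer(),
                            score = numeric())
  write.csv(scores, file.path(dir, "scores.csv"), row.names = FALSE, quote = FALSE)
  write.csv(frames, file.path(dir, "frames.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read instance-candidate sets written by [write_candidate_sets()]
#'
#' @param dir directory holding the candidate masks and score tables.
#' @return list of [candidate_set()] objects ordered by frame index.
#' @export
read_candidate_sets <- function(dir) {
  sc <- read.csv(file.path(dir, "scores.csv"))
  fr <- read.csv(file.path(dir, "frames.csv"))
  out <- vector("list", nrow(fr))
  for (i in seq_len(nrow(fr))) {
    fi <- fr$frame_index[i]
    rows <- sc[sc$frame_index == fi, , drop = FALSE]
    rows <- rows[order(rows$candidate_index), , drop = FALSE]
    masks <- lapply(rows$candidate_index, function(k) {
      read_one_image(file.path(dir, sprintf("frame_%06d_cand_%03d.png", fi, k)))
    })
    out[[i]] <- candidate_set(fi, masks, rows$score, dim = c(fr$h[i], fr$w[i]))
  }
  out[order(vapply(out, `[[`, integer(1), "frame_index"))]
}

#' Read a manual phase annotation
#'
#' @param path CSV with columns `start`, `end`, `label`.
#' @return a [phase_annotation()].
#' @export
read_phase_annotation <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("start", "end", "label"), names(df))
  if (length(miss)) stopf("annotation %s is missing columns: %s", path,
                          paste(miss, collapse = ", "))
  phase_annotation(df$start, df$end, df$label)
}

#' Write a manual phase annotation
#'
#' @param ann a [phase_annotation()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_phase_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "phase_annotation"))
  write.csv(as.data.frame(ann), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
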