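#' Binary mask frame
#'
#' One binary segmentation mask on an image grid. Pixels are stored as an
#' integer matrix with values in `{0, 1}`; rows are image rows (y, downward),
#' columns are image columns (x, rightward).
#'
#' @param pixels matrix (or logical matrix) of mask values; any non-zero value
#'   is coerced to 1.
#' @param frame_index non-negative integer position of the frame within the
#'   sampled sequence.
#' @return an object of class `mask_frame`: the pixel matrix with attributes
#'   `frame_index` and class.
#' @examples
#' m <- mask_frame(matrix(c(0, 1, 1, 0), 2, 2), frame_index = 0)
#' compute_csa(m)
#' @export
mask_frame <- function(pixels, frame_index = 0L) {
  if (is.logical(pixels)) storage.mode(pixels) <- "integer"
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("pixels must be a numeric or logical matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stopf("mask must have at least one row and one column")
  bad <- !(pixels %in% c(0, 1))
  if (any(bad)) stopf("mask values must be exactly 0 or 1 (%d offending pixels)",
                      sum(bad))
  if (!is_count(frame_index)) stopf("frame_index must be a non-negative integer")
  m <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  structure(m, frame_index = as.integer(frame_index), class = "mask_frame")
}

#' @export
print.mask_frame <- function(x, ...) {
  cat(sprintf("<mask_frame> %d x %d, frame_index %d, foreground %d px\n",
              nrow(x), ncol(x), attr(x, "frame_index"), sum(x)))
  invisible(x)
}

frame_index_of <- function(frame) {
  fi <- attr(frame, "frame_index")
  if (is.null(fi)) 0L else fi
}

# strip class/attributes down to a plain integer matrix
as_pixel_matrix <- function(frame) {
  matrix(as.integer(frame), nrow(frame), ncol(frame))
}

#' Acquisition metadata for a mask sequence
#'
#' @param px_per_cm pixels per centimetre of the image grid (mandatory; the
#'   scale is device-dependent and carried as metadata).
#' @param fps acquisition frame rate in frames/second (default 38).
#' @param frame_step every `frame_step`-th acquired frame is present in the
#'   sequence (default 4); the effective sampling interval is
#'   `dt = frame_step / fps` seconds.
#' @param axis_labels optional character pair naming the anatomical sense of
#'   +x and +y (e.g. `c(x = "scaphoid (radial)", y = "palmar")`).
#' @return an object of class `sequence_meta`.
#' @export
sequence_meta <- function(px_per_cm, fps = 38, frame_step = 4L, axis_labels = NULL) {
  if (!is_number(px_per_cm) || px_per_cm <= 0) stopf("px_per_cm must be > 0")
  if (!is_number(fps) || fps <= 0) stopf("fps must be > 0")
  if (!is_count(frame_step, min = 1L)) stopf("frame_step must be an integer >= 1")
  structure(list(px_per_cm = px_per_cm, fps = fps,
                 frame_step = as.integer(frame_step),
                 axis_labels = axis_labels),
            class = "sequence_meta")
}

#' Effective sampling interval of a sequence
#'
#' @param meta a `sequence_meta` or `mask_sequence`.
#' @return `frame_step / fps` in seconds.
#' @export
sampling_interval <- function(meta) {
  if (inherits(meta, "mask_sequence")) meta <- meta$meta
  stopifnot(inherits(meta, "sequence_meta"))
  meta$frame_step / meta$fps
}

#' @export
print.sequence_meta <- function(x, ...) {
  cat(sprintf("<sequence_meta> fps %g, frame_step %d (dt = %.4f s), px_per_cm %g\n",
              x$fps, x$frame_step, sampling_interval(x), x$px_per_cm))
  invisible(x)
}

#' Ordered sequence of mask frames with acquisition metadata
#'
#' @param frames list of [mask_frame()] objects with strictly increasing
#'   `frame_index` and identical dimensions.
#' @param meta a [sequence_meta()].
#' @return an object of class `mask_sequence` (a list with elements `frames`
#'   and `meta`).
#' @export
mask_sequence <- function(frames, meta) {
  if (!inherits(meta, "sequence_meta")) stopf("meta must be a sequence_meta")
  if (!is.list(frames) || length(frames) == 0L)
    stopf("a mask sequence must contain at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "mask_frame")))
    stopf("all frames must be mask_frame objects")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    off <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    stopf("inconsistent frame dimensions: frame %d is %dx%d, expected %dx%d",
          off, dims[1, off], dims[2, off], dims[1, 1], dims[2, 1])
  }
  fi <- vapply(frames, frame_index_of, integer(1))
  if (any(diff(fi) <= 0)) stopf("frame_index must be strictly increasing")
  structure(list(frames = frames, meta = meta), class = "mask_sequence")
}

#' @export
length.mask_sequence <- function(x) length(x$frames)

#' @export
print.mask_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<mask_sequence> %d frames of %d x %d, dt = %.4f s, px_per_cm %g\n",
              length(x$frames), d[1], d[2], sampling_interval(x),
              x$meta$px_per_cm))
  invisible(x)
}

#' Instance-segmentation candidate set for one frame
#'
#' Holds the scored candidate masks an instance-segmentation model proposed
#' for a single frame. The list may be empty (no detection).
#'
#' @param frame_index frame position the candidates belong to.
#' @param masks list of binary mask matrices (all of dimension `dim`).
#' @param scores numeric confidence scores in `[0, 1]`, one per mask.
#' @param dim integer image dimensions `c(h, w)`; inferred from `masks` when
#'   non-empty.
#' @return an object of class `candidate_set`.
#' @export
candidate_set <- function(frame_index, masks = list(), scores = numeric(), dim = NULL) {
  if (length(masks) != length(scores))
    stopf("masks and scores must have the same length")
  if (length(scores) && (any(!is.finite(scores)) || any(scores < 0 | scores > 1)))
    stopf("scores must lie in [0, 1]")
  masks <- lapply(masks, binarize)
  if (length(masks)) {
    dims <- vapply(masks, dim, integer(2))
    if (any(dims != dims[, 1])) stopf("candidate masks must share dimensions")
    dim <- dims[, 1]
  } else if (is.null(dim)) {
    stopf("dim = c(h, w) is required for an empty candidate set")
  }
  structure(list(frame_index = as.integer(frame_index), masks = masks,
                 scores = as.numeric(scores), dim = as.integer(dim)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> frame %d: %d candidates%s\n", x$frame_index,
              length(x$masks),
              if (length(x$scores))
                sprintf(" (scores %s)", paste(signif(x$scores, 3), collapse = ", "))
              else ""))
  invisible(x)
}

#' Manual phase annotation
#'
#' @param start,end integer frame indices delimiting each phase (inclusive).
#' @param label character vector of phase labels, `"flexion"` or
#'   `"extension"`; labels must alternate and intervals must be ordered and
#'   non-overlapping (adjacent phases may share a boundary frame).
#' @return an object of class `phase_annotation` (a data frame).
#' @export
phase_annotation <- function(start, end, label) {
  if (length(start) != length(end) || length(start) != length(label))
    stopf("start, end and label must have equal length")
  label <- as.character(label)
  if (!all(label %in% c("flexion", "extension")))
    stopf("labels must be 'flexion' or 'extension'")
  if (any(end <= start)) stopf("each phase must satisfy end > start")
  if (length(start) > 1L) {
    if (any(diff(start) <= 0)) stopf("phases must be ordered by start")
    if (any(start[-1] < end[-length(end)]))
      stopf("phases must not overlap (shared boundary frames are allowed)")
    if (any(label[-1] == label[-length(label)]))
      stopf("phase labels must alternate")
  }
  structure(data.frame(start = as.integer(start), end = as.integer(end),
                       label = label, stringsAsFactors = FALSE),
            class = c("phase_annotation", "data.frame"))
}
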