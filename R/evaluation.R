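#' Intersection over union of two masks
#'
#' `|A intersect B| / |A union B|`. Both masks empty scores 1 (nothing to
#' segment, nothing segmented); exactly one empty scores 0.
#'
#' @param a,b [mask_frame()] objects or binary matrices of equal dimensions.
#' @return IoU in `[0, 1]`.
#' @export
compute_iou <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stopf("dimension mismatch: %dx%d vs %dx%d", nrow(a), ncol(a), nrow(b), ncol(b))
  ai <- as.integer(a); bi <- as.integer(b)
  inter <- sum(ai & bi)
  uni <- sum(ai | bi)
  if (uni == 0L) return(1)
  inter / uni
}

#' Per-frame and per-video IoU of a predicted mask sequence
#'
#' Computes the IoU of each predicted frame against the matching ground-truth
#' frame and the per-video average IoU. Invalid predictions (empty masks)
#' count as IoU 0 by default — the per-video average is taken over all sampled
#' frames — or are excluded when `skip_invalid = TRUE`.
#'
#' @param pred,truth [mask_sequence()] objects of equal length and dimensions.
#' @param skip_invalid exclude frames with an empty prediction from the
#'   average instead of counting them as 0.
#' @return an object of class `iou_report`: list with `per_frame` (data frame
#'   `frame_index`, `iou`, `valid`), `video_average_iou`, `n_frames` (frames
#'   counted in the average) and `policy` (`"counted"` or `"skipped"`).
#' @export
evaluate_video <- function(pred, truth, skip_invalid = FALSE) {
  stopifnot(inherits(pred, "mask_sequence"), inherits(truth, "mask_sequence"))
  if (length(pred$frames) != length(truth$frames))
    stopf("length mismatch: %d predicted vs %d truth frames",
          length(pred$frames), length(truth$frames))
  n <- length(pred$frames)
  iou <- numeric(n); valid <- logical(n); fi <- integer(n)
  for (i in seq_len(n)) {
    p <- pred$frames[[i]]; g <- truth$frames[[i]]
    fi[i] <- frame_index_of(p)
    valid[i] <- sum(p) > 0L
    iou[i] <- compute_iou(p, g)
  }
  counted <- if (skip_invalid) valid else rep(TRUE, n)
  avg <- if (any(counted)) mean(iou[counted]) else NA_real_
  structure(list(per_frame = data.frame(frame_index = fi, iou = iou,
                                        valid = valid),
                 video_average_iou = avg,
                 n_frames = sum(counted),
                 policy = if (skip_invalid) "skipped" else "counted"),
            class = "iou_report")
}

#' @export
print.iou_report <- function(x, ...) {
  cat(sprintf("<iou_report> %d frames counted (invalid frames %s)\n",
              x$n_frames, x$policy))
  cat(sprintf("  video average IoU: %.4f\n", x$video_average_iou))
  invisible(x)
}
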