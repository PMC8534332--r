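#' Cross-sectional area of a mask (zeroth moment)
#'
#' The cross-sectional area (CSA) is the zeroth image moment of the binary
#' mask, i.e. the total number of foreground pixels.
#'
#' @param mask a [mask_frame()] or binary matrix.
#' @return integer pixel count (0 for an empty mask).
#' @export
compute_csa <- function(mask) {
  sum(as.integer(mask))
}

#' Centroid of a mask (first moments)
#'
#' The centroid is the first image moment divided by the area:
#' `cx = sum(x * f(x, y)) / CSA`, `cy = sum(y * f(x, y)) / CSA`, in 0-based
#' image coordinates (x = column index rightward, y = row index downward).
#'
#' @param mask a [mask_frame()] or binary matrix.
#' @return named numeric `c(cx, cy)` in pixels.
#' @export
compute_centroid <- function(mask) {
  csa <- compute_csa(mask)
  if (csa < 1L) stopf("cannot compute the centroid of an empty mask")
  m <- as.integer(mask)
  x <- as.numeric(col(mask)) - 1
  y <- as.numeric(row(mask)) - 1
  c(cx = sum(x * m) / csa, cy = sum(y * m) / csa)
}

# Moore-neighbour border following with Jacob's stopping criterion.
# Returns the ordered outer-border pixels as a k x 2 (row, col) matrix,
# 1-based, clockwise in image coordinates (y down).
moore_trace <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0L, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  idx <- which(p == 1L)
  rows <- ((idx - 1L) %% nrow(p)) + 1L
  cols <- ((idx - 1L) %/% nrow(p)) + 1L
  ord <- order(rows, cols)
  start <- c(rows[ord[1]], cols[ord[1]])
  # clockwise neighbourhood starting at W (y grows downward):
  nb <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
              c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  boundary <- matrix(NA_integer_, sum(p) * 4L + 8L, 2L)
  boundary[1L, ] <- start
  nb_pts <- 1L
  cur <- start
  backtrack <- 1L  # entered the start pixel from the west (raster scan)
  first_next <- NULL
  repeat {
    moved <- FALSE
    for (i in 0:7) {
      j <- ((backtrack - 1L + i) %% 8L) + 1L
      cand <- cur + nb[j, ]
      if (p[cand[1], cand[2]] == 1L) {
        prevj <- ((j - 2L) %% 8L) + 1L
        prevpos <- cur + nb[prevj, ]
        d <- prevpos - cand
        backtrack <- which(nb[, 1] == d[1] & nb[, 2] == d[2])
        cur <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) break  # isolated pixel: boundary is the single start pixel
    if (is.null(first_next)) {
      first_next <- cur
    } else if (all(cur == first_next) && all(boundary[nb_pts, ] == start)) {
      nb_pts <- nb_pts - 1L  # drop the duplicated start before the repeat
      break
    }
    nb_pts <- nb_pts + 1L
    boundary[nb_pts, ] <- cur
  }
  boundary[seq_len(nb_pts), , drop = FALSE] - 1L  # un-pad
}

#' Trace the outer perimeter of a single-component mask
#'
#' Follows the outer border of the (single) 8-connected foreground component
#' with Moore-neighbour border following. The boundary polygon has vertices at
#' foreground pixel centres joined by 8-connected steps; its length is the sum
#' of Euclidean distances between consecutive vertices including the closing
#' segment (axis step 1, diagonal step `sqrt(2)`). No sub-pixel smoothing or
#' corner-count correction is applied, so the length carries the classical
#' digital-perimeter bias (up to roughly +5 percent on smooth convex shapes);
#' circularity values inherit that bias squared.
#'
#' @param mask a [mask_frame()] or binary matrix with exactly one 8-connected
#'   foreground component of area at least `min_area`.
#' @param min_area smallest area (pixels) for which a perimeter is considered
#'   meaningful; default 5.
#' @return list with `boundary` (k x 2 matrix of 0-based `(x, y)` pixel-centre
#'   vertices, in traversal order) and `length` (pixels).
#' @export
trace_perimeter <- function(mask, min_area = 5L) {
  m <- as_pixel_matrix(mask)
  area <- sum(m)
  if (area < min_area)
    stopf("mask area %d is below min_area = %d; perimeter undefined", area, min_area)
  regs <- label_regions(m)
  if (length(regs) > 1L)
    stopf("mask has %d 8-connected components; post-process to one region first",
          length(regs))
  b <- moore_trace(m)
  xy <- cbind(x = b[, 2] - 1L, y = b[, 1] - 1L)
  len <- if (nrow(xy) < 2L) 0 else {
    d <- diff(rbind(xy, xy[1L, , drop = FALSE]))
    sum(sqrt(rowSums(d^2)))
  }
  list(boundary = xy, length = len)
}

#' Circularity from area and perimeter
#'
#' `circularity = 4 * pi * CSA / perimeter^2`: 1 for an ideal circle, about
#' 0.605 for an equilateral triangle, smaller for less round shapes. The value
#' is not clipped; small pixelated shapes can exceed 1.
#'
#' @param csa area in pixels (or any consistent unit).
#' @param perimeter perimeter in the matching unit; must be positive.
#' @return dimensionless circularity.
#' @export
compute_circularity <- function(csa, perimeter) {
  if (!is_number(perimeter) || perimeter <= 0) stopf("perimeter must be > 0")
  4 * pi * csa / perimeter^2
}

#' Convert pixel metrics of one record to physical units
#'
#' Divides lengths by `px_per_cm` and areas by `px_per_cm^2`; circularity is
#' dimensionless and unchanged.
#'
#' @param record list or one-row data frame with fields `csa_px`,
#'   `perimeter_px`, `cx_px`, `cy_px` (NA allowed).
#' @param px_per_cm pixels per centimetre, positive.
#' @return `record` with `csa_cm2`, `perimeter_cm`, `cx_cm`, `cy_cm` filled in.
#' @export
to_physical <- function(record, px_per_cm) {
  if (!is_number(px_per_cm) || px_per_cm <= 0) stopf("px_per_cm must be > 0")
  record$csa_cm2 <- record$csa_px / px_per_cm^2
  record$perimeter_cm <- record$perimeter_px / px_per_cm
  record$cx_cm <- record$cx_px / px_per_cm
  record$cy_cm <- record$cy_px / px_per_cm
  record
}

#' Fill enclosed holes in a mask
#'
#' Background regions (4-connected) that do not touch the image border are
#' interior holes; they are set to foreground.
#'
#' @param mask a [mask_frame()] or binary matrix.
#' @return binary matrix with holes filled.
#' @export
fill_mask_holes <- function(mask) {
  m <- as_pixel_matrix(mask)
  bg <- EBImage::bwlabel(1L - m)  # 4-connected background components
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  hole <- bg > 0 & !(bg %in% border_labels)
  m[hole] <- 1L
  m
}

empty_record <- function(frame_index, time_s) {
  data.frame(frame_index = frame_index, time_s = time_s, csa_px = NA_real_,
             csa_cm2 = NA_real_, cx_px = NA_real_, cy_px = NA_real_,
             cx_cm = NA_real_, cy_cm = NA_real_, perimeter_px = NA_real_,
             perimeter_cm = NA_real_, circularity = NA_real_,
             step_displacement_cm = NA_real_, valid = FALSE)
}

#' Per-frame morphology metrics of a mask sequence
#'
#' Computes, for every frame, the cross-sectional area (pixel count and cm2),
#' centroid (pixels and cm), outer perimeter (chain-code arc length),
#' circularity, and the Euclidean centroid displacement since the previous
#' frame (`step_displacement_cm`, NA for the first frame and after an invalid
#' frame). Frame time is `position * dt` with `dt = frame_step / fps`.
#'
#' Frames whose (post-processed) mask is empty or smaller than `min_area`
#' pixels are flagged invalid: their metric fields are NA and `valid` is
#' FALSE. With `postprocess = "none"`, a frame holding several disconnected
#' regions is an error (post-process first).
#'
#' @param seq a [mask_sequence()].
#' @param postprocess `"none"` (frames must already be single-region),
#'   `"semantic"` (largest-area rule, [select_semantic_region()]) or
#'   `"instance"` (highest-confidence candidate, [select_instance_candidate()];
#'   requires `candidates`).
#' @param candidates list of [candidate_set()] objects matched to frames by
#'   `frame_index` (instance mode only).
#' @param fill_holes if TRUE, interior holes are filled before the area and
#'   centroid are computed (the perimeter always follows the outer border).
#' @param min_area validity threshold in pixels (default 5).
#' @return data frame with columns `frame_index`, `time_s`, `csa_px`,
#'   `csa_cm2`, `cx_px`, `cy_px`, `cx_cm`, `cy_cm`, `perimeter_px`,
#'   `perimeter_cm`, `circularity`, `step_displacement_cm`, `valid`.
#' @export
sequence_metrics <- function(seq, postprocess = c("none", "semantic", "instance"),
                             candidates = NULL, fill_holes = FALSE,
                             min_area = 5L) {
  stopifnot(inherits(seq, "mask_sequence"))
  postprocess <- match.arg(postprocess)
  if (postprocess == "instance" && is.null(candidates))
    stopf("instance post-processing needs the candidate sets")
  dt <- sampling_interval(seq)
  px <- seq$meta$px_per_cm
  n <- length(seq$frames)
  cand_index <- if (!is.null(candidates))
    vapply(candidates, `[[`, integer(1), "frame_index") else integer()
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fr <- seq$frames[[i]]
    fi <- frame_index_of(fr)
    t_s <- (i - 1L) * dt
    m <- switch(postprocess,
      none = as_pixel_matrix(fr),
      semantic = as_pixel_matrix(select_semantic_region(fr)),
      instance = {
        j <- match(fi, cand_index)
        if (is.na(j)) stopf("no candidate set for frame_index %d", fi)
        as_pixel_matrix(select_instance_candidate(candidates[[j]]))
      })
    area_raw <- sum(m)
    if (area_raw < min_area) { out[[i]] <- empty_record(fi, t_s); next }
    if (postprocess == "none" && length(label_regions(m)) > 1L)
      stopf("frame_index %d has multiple disconnected regions; apply post-processing",
            fi)
    per <- tryCatch(trace_perimeter(m, min_area = min_area),
                    error = function(e) stopf("frame_index %d: %s", fi,
                                              conditionMessage(e)))
    mm <- if (fill_holes) fill_mask_holes(m) else m
    csa <- compute_csa(mm)
    cen <- compute_centroid(mm)
    rec <- data.frame(frame_index = fi, time_s = t_s, csa_px = as.numeric(csa),
                      csa_cm2 = NA_real_, cx_px = cen[["cx"]], cy_px = cen[["cy"]],
                      cx_cm = NA_real_, cy_cm = NA_real_,
                      perimeter_px = per$length, perimeter_cm = NA_real_,
                      circularity = compute_circularity(csa, per$length),
                      step_displacement_cm = NA_real_, valid = TRUE)
    out[[i]] <- to_physical(rec, px)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  for (i in seq_len(n)[-1]) {
    if (df$valid[i] && df$valid[i - 1L]) {
      df$step_displacement_cm[i] <- sqrt((df$cx_cm[i] - df$cx_cm[i - 1L])^2 +
                                         (df$cy_cm[i] - df$cy_cm[i - 1L])^2)
    }
  }
  df
}
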