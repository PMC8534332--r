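# centered moving average; near the ends the window shrinks symmetrically so
# the output has the same length and no phase lag
smooth_ma <- function(x, window) {
  n <- length(x)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(half, i - 1L, n - i)
    out[i] <- mean(x[(i - k):(i + k)])
  }
  out
}

# linearly bridge NA values (any run length) for detection purposes
bridge_na <- function(x, t) {
  ok <- !is.na(x)
  if (all(ok)) return(x)
  if (sum(ok) < 2L) stopf("fewer than 2 valid values; cannot interpolate")
  approx(t[ok], x[ok], xout = t, rule = 2)$y
}

# indices of strict local extrema of x (plateaus contribute their first
# index); returns integer positions, alternating maxima/minima by construction
local_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(integer())
  # carry the previous non-zero sign across plateaus
  sa <- s
  last <- 0
  for (i in seq_along(sa)) {
    if (sa[i] == 0) sa[i] <- last else last <- sa[i]
  }
  ext <- integer()
  for (i in seq_len(length(sa) - 1L)) {
    if (sa[i] != 0 && sa[i + 1L] != 0 && sa[i] != sa[i + 1L])
      ext <- c(ext, i + 1L)
  }
  ext
}

# prune alternating extrema: iteratively drop the adjacent pair with the
# smallest absolute swing until all swings >= thresh; keeps alternation
prune_extrema <- function(ext, x, thresh) {
  while (length(ext) >= 2L) {
    swings <- abs(diff(x[ext]))
    k <- which.min(swings)
    if (swings[k] >= thresh) break
    ext <- ext[-c(k, k + 1L)]
  }
  ext
}

# refine each turning point found on the smoothed trace by intersecting the
# two motion limbs of the raw trace: the moving average flattens asymmetric
# vertices and can drag the turning point a frame into the gentler slope,
# truncating every phase. A line is least-squares fitted to `side` raw frames
# on each flank (the frames adjacent to the vertex are excluded: they mix the
# two limbs), and the boundary snaps to the frame nearest the intersection.
# Exact for piecewise-linear motion; falls back to the unrefined position at
# the series ends or if refinement breaks the strict ordering.
refine_extrema <- function(ext, raw, side = 3L) {
  if (length(ext) < 2L || side < 2L) return(ext)
  n <- length(raw)
  fit_line <- function(w) {
    mx <- mean(w); my <- mean(raw[w])
    a <- sum((w - mx) * (raw[w] - my)) / sum((w - mx)^2)
    c(slope = a, intercept = my - a * mx)
  }
  out <- ext
  for (i in seq_along(ext)) {
    e <- ext[i]
    wl <- max(1L, e - 1L - side):(e - 1L)
    wr <- (e + 1L):min(n, e + 1L + side)
    if (wl[1] < 1L || wr[length(wr)] > n || length(wl) < 2L || length(wr) < 2L)
      next
    fl <- fit_line(wl); fr <- fit_line(wr)
    if (abs(fl[["slope"]] - fr[["slope"]]) < 1e-12) next
    v <- (fr[["intercept"]] - fl[["intercept"]]) / (fl[["slope"]] - fr[["slope"]])
    out[i] <- max(1L, min(n, as.integer(round(v))))
  }
  if (any(diff(out) <= 0L)) ext else out
}

phase_label_of <- function(x_start, x_end) {
  if (x_end < x_start) "flexion" else "extension"
}

build_phase <- function(records, start_row, end_row, label, flex_ref) {
  tr <- records[start_row:end_row, , drop = FALSE]
  rownames(tr) <- NULL
  # centroid offset relative to the centroid at the start of the enclosing
  # flexion phase (flex_ref = c(cx_cm, cy_cm))
  tr$centroid_offset_cm <- sqrt((tr$cx_cm - flex_ref[1])^2 +
                                (tr$cy_cm - flex_ref[2])^2)
  inval <- !tr$valid
  pooling_ok <- !inval[1] && !inval[nrow(tr)] && max_run(inval) <= 2L
  structure(list(label = label,
                 start = start_row, end = end_row,
                 frame_start = records$frame_index[start_row],
                 frame_end = records$frame_index[end_row],
                 duration_s = records$time_s[end_row] - records$time_s[start_row],
                 n_frames = end_row - start_row + 1L,
                 trace = tr,
                 pooling_ok = pooling_ok),
            class = "nerve_phase")
}

#' @export
print.nerve_phase <- function(x, ...) {
  cat(sprintf("<nerve_phase> %s, frames %d-%d (%d frames, %.3f s)%s\n",
              x$label, x$frame_start, x$frame_end, x$n_frames, x$duration_s,
              if (x$pooling_ok) "" else " [excluded from pooling]"))
  invisible(x)
}

#' Split a metric trace into flexion and extension phases
#'
#' In `"annotated"` mode the phases are returned exactly as annotated. In
#' `"automatic"` mode the biphasic pattern of the centroid x-coordinate is
#' used: `cx` is smoothed with a centered moving average (`window_frames`),
#' alternating local extrema are kept when the swing between neighbouring
#' extrema is at least `prominence_frac` times the total range of the smoothed
#' trace, each turning point is then refined by intersecting least-squares
#' line fits to the two raw-trace motion limbs flanking it (the moving
#' average lags asymmetric vertices; the intersection is exact for
#' piecewise-linear motion), each inter-extremum run becomes one phase, and
#' phases shorter than `min_phase_s` are merged into their neighbours. A
#' phase is labelled
#' `"flexion"` when the net `cx` change is negative (the nerve moves toward
#' the ulnar side during flexion when +x points to the scaphoid/radial side),
#' `"extension"` otherwise.
#'
#' Each phase's trace gains a `centroid_offset_cm` column: the per-frame
#' Euclidean deviation of the centroid from its position at the start of the
#' enclosing flexion phase (for an extension phase, the start of the
#' preceding flexion phase; a leading extension phase uses its own start).
#'
#' Invalid frames inside a phase are tolerated up to 2 consecutive (they are
#' linearly bridged when profiles are resampled); longer gaps, or an invalid
#' boundary frame, mark the phase as excluded from pooling.
#'
#' @param records metrics data frame from [sequence_metrics()] (needs
#'   `time_s`, `cx_cm`, `cy_cm`, `valid`).
#' @param mode `"automatic"` or `"annotated"`.
#' @param annotation a [phase_annotation()] (annotated mode); `start`/`end`
#'   refer to `frame_index` values present in `records`.
#' @param window_frames moving-average window for the detector (default 5).
#' @param prominence_frac minimum extremum swing as a fraction of the total
#'   smoothed-cx range (default 0.10).
#' @param min_phase_s phases shorter than this are merged (default 0.2 s).
#' @return an object of class `phase_set`: a list of phases. Zero phases (with
#'   a warning) when fewer than two qualifying extrema are found.
#' @export
segment_phases <- function(records, mode = c("automatic", "annotated"),
                           annotation = NULL, window_frames = 5L,
                           prominence_frac = 0.10, min_phase_s = 0.2) {
  mode <- match.arg(mode)
  if (!is.data.frame(records) || sum(records$valid) < 2L)
    stopf("need at least 2 valid records")
  n <- nrow(records)
  if (mode == "annotated") {
    if (!inherits(annotation, "phase_annotation"))
      stopf("annotated mode needs a phase_annotation")
    rows_start <- match(annotation$start, records$frame_index)
    rows_end <- match(annotation$end, records$frame_index)
    if (anyNA(rows_start) || anyNA(rows_end))
      stopf("annotation refers to frame indices absent from the records")
    phases <- vector("list", nrow(annotation))
    flex_ref <- c(records$cx_cm[rows_start[1]], records$cy_cm[rows_start[1]])
    for (i in seq_len(nrow(annotation))) {
      if (annotation$label[i] == "flexion")
        flex_ref <- c(records$cx_cm[rows_start[i]], records$cy_cm[rows_start[i]])
      phases[[i]] <- build_phase(records, rows_start[i], rows_end[i],
                                 annotation$label[i], flex_ref)
    }
    return(structure(phases, class = "phase_set"))
  }

  cx <- bridge_na(records$cx_cm, records$time_s)
  sm <- smooth_ma(cx, window_frames)
  rng <- diff(range(sm))
  ext <- local_extrema(sm)
  if (rng > 0) ext <- prune_extrema(ext, sm, prominence_frac * rng)
  if (length(ext) < 2L) {
    warning("no phases: fewer than 2 qualifying extrema in the centroid trace")
    return(structure(list(), class = "phase_set"))
  }
  ext <- refine_extrema(ext, cx)
  # merge phases shorter than min_phase_s: drop the bounding extrema of the
  # offending run (both when interior, the interior one at the ends)
  repeat {
    dur <- diff(records$time_s[ext])
    short <- which(dur < min_phase_s)
    if (length(short) == 0L || length(ext) < 3L) break
    k <- short[which.min(dur[short])]
    drop <- if (k == 1L) 2L
            else if (k == length(ext) - 1L) length(ext) - 1L
            else c(k, k + 1L)
    ext <- ext[-drop]
    if (length(ext) < 2L) break
  }
  if (length(ext) < 2L) {
    warning("no phases: all candidate phases were shorter than min_phase_s")
    return(structure(list(), class = "phase_set"))
  }
  phases <- vector("list", length(ext) - 1L)
  flex_ref <- NULL
  for (i in seq_len(length(ext) - 1L)) {
    s <- ext[i]; e <- ext[i + 1L]
    lab <- phase_label_of(sm[s], sm[e])
    if (lab == "flexion" || is.null(flex_ref))
      flex_ref <- c(records$cx_cm[s], records$cy_cm[s])
    if (is.na(flex_ref[1]))
      flex_ref <- c(cx[s], bridge_na(records$cy_cm, records$time_s)[s])
    phases[[i]] <- build_phase(records, s, e, lab, flex_ref)
  }
  structure(phases, class = "phase_set")
}

#' @export
print.phase_set <- function(x, ...) {
  cat(sprintf("<phase_set> %d phases (%d flexion, %d extension)\n", length(x),
              sum(vapply(x, `[[`, character(1), "label") == "flexion"),
              sum(vapply(x, `[[`, character(1), "label") == "extension")))
  invisible(x)
}

#' @export
summary.phase_set <- function(object, ...) {
  if (length(object) == 0L) {
    cat("<phase_set> empty\n")
    return(invisible(NULL))
  }
  df <- data.frame(
    label = vapply(object, `[[`, character(1), "label"),
    frame_start = vapply(object, `[[`, integer(1), "frame_start"),
    frame_end = vapply(object, `[[`, integer(1), "frame_end"),
    n_frames = vapply(object, `[[`, integer(1), "n_frames"),
    duration_s = vapply(object, `[[`, numeric(1), "duration_s"),
    pooling_ok = vapply(object, `[[`, logical(1), "pooling_ok"))
  print(df)
  invisible(df)
}

phase_durations <- function(phases, label) {
  labs <- vapply(phases, `[[`, character(1), "label")
  vapply(phases[labs == label], `[[`, numeric(1), "duration_s")
}

#' Histogram of phase durations with D90 and D50 modal ranges
#'
#' Bins phase durations into fixed-width bins starting at 0 and reports the
#' D90 and D50 ranges: the contiguous run of bins containing the modal bin
#' whose counts are at least 90 percent (respectively 50 percent) of the
#' maximum count. Isolated distant bins above threshold are excluded; ties
#' for the modal bin resolve to the shortest duration. By construction
#' D90 is contained in D50 and both contain the mode.
#'
#' @param phases a `phase_set` from [segment_phases()].
#' @param label `"flexion"` or `"extension"`.
#' @param bin_width_s histogram bin width in seconds (default 0.03).
#' @return an object of class `duration_histogram` with elements
#'   `bin_width_s`, `bin_edges`, `counts`, `durations`, `label`,
#'   `d90_range_s`, `d50_range_s`.
#' @export
duration_histogram <- function(phases, label = c("flexion", "extension"),
                               bin_width_s = 0.03) {
  label <- match.arg(label)
  durs <- phase_durations(phases, label)
  if (length(durs) == 0L) stopf("no phases labelled '%s'", label)
  if (!is_number(bin_width_s) || bin_width_s <= 0) stopf("bin_width_s must be > 0")
  nbin <- max(1L, ceiling(max(durs) / bin_width_s + 1e-9))
  edges <- seq(0, by = bin_width_s, length.out = nbin + 1L)
  if (max(durs) >= edges[length(edges)])  # duration exactly on the last edge
    edges <- c(edges, edges[length(edges)] + bin_width_s)
  # bins are [edge_i, edge_{i+1})
  bin <- findInterval(durs, edges, left.open = FALSE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  mode_bin <- which.max(counts)  # first maximal bin
  d_range <- function(p) {
    thr <- p * counts[mode_bin]
    lo <- mode_bin
    while (lo > 1L && counts[lo - 1L] >= thr) lo <- lo - 1L
    hi <- mode_bin
    while (hi < length(counts) && counts[hi + 1L] >= thr) hi <- hi + 1L
    c(edges[lo], edges[hi + 1L])
  }
  structure(list(bin_width_s = bin_width_s, bin_edges = edges, counts = counts,
                 durations = durs, label = label, mode_bin = mode_bin,
                 d90_range_s = d_range(0.9), d50_range_s = d_range(0.5)),
            class = "duration_histogram")
}

#' @export
print.duration_histogram <- function(x, ...) {
  cat(sprintf("<duration_histogram> %s: %d phases, bin width %.3g s\n",
              x$label, length(x$durations), x$bin_width_s))
  cat(sprintf("  D90: %.3f-%.3f s, D50: %.3f-%.3f s\n",
              x$d90_range_s[1], x$d90_range_s[2],
              x$d50_range_s[1], x$d50_range_s[2]))
  invisible(x)
}

#' @export
plot.duration_histogram <- function(x, ...) {
  mids <- head(x$bin_edges, -1) + x$bin_width_s / 2
  barplot(x$counts, names.arg = sprintf("%.2f", mids), space = 0,
          xlab = "phase duration (s)", ylab = "count",
          main = sprintf("%s phase durations", x$label), ...)
  abline(h = 0.9 * max(x$counts), lty = 3)
  abline(h = 0.5 * max(x$counts), lty = 2)
  legend("topright", lty = c(3, 2), legend = c("90% of max", "50% of max"),
         bty = "n")
  invisible(x)
}
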