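#' Resample one phase's metric trace onto the 30-point normalized-time grid
#'
#' Frame times are mapped affinely onto `[0, 1]` and the metric is linearly
#' interpolated at `u_k = k / 29, k = 0..29`; the first and last output values
#' equal the first and last input values exactly. Invalid frames inside the
#' phase are linearly bridged when at most 2 consecutive; longer gaps (or an
#' invalid boundary frame) are an error — such phases are excluded from
#' pooling.
#'
#' @param phase a `nerve_phase` from [segment_phases()].
#' @param metric name of a column of the phase trace (e.g. `"csa_cm2"`,
#'   `"perimeter_cm"`, `"circularity"`, `"centroid_offset_cm"`).
#' @param n_points number of grid points (default 30).
#' @return numeric vector of `n_points` resampled values.
#' @export
resample_normalized <- function(phase, metric, n_points = 30L) {
  stopifnot(inherits(phase, "nerve_phase"))
  tr <- phase$trace
  if (!metric %in% names(tr)) stopf("metric '%s' not found in the phase trace", metric)
  v <- tr[[metric]]
  t <- tr$time_s
  ok <- !is.na(v)
  if (sum(ok) < 2L) stopf("fewer than 2 valid values for metric '%s'", metric)
  if (!ok[1] || !ok[length(ok)])
    stopf("phase boundary frame has no valid '%s' value", metric)
  if (max_run(!ok) > 2L)
    stopf("more than 2 consecutive invalid frames; phase disqualified")
  if (any(!ok)) v <- approx(t[ok], v[ok], xout = t)$y
  u <- (t - t[1]) / (t[length(t)] - t[1])
  grid <- seq(0, 1, length.out = n_points)
  out <- approx(u, v, xout = grid)$y
  out[1] <- v[1]
  out[n_points] <- v[length(v)]
  out
}

#' Pool normalized phase profiles into a mean +/- SD temporal profile
#'
#' Resamples every qualifying phase onto the 30-point normalized-time grid and
#' reports the per-point mean and sample standard deviation (n - 1
#' denominator). Phases qualify when they carry the requested label, pass the
#' duration filter (e.g. a D90 or D50 range from [duration_histogram()]), and
#' are not disqualified by segmentation gaps.
#'
#' @param phases a `phase_set`.
#' @param metric trace column to pool (see [resample_normalized()]).
#' @param label `"flexion"` or `"extension"`.
#' @param duration_filter optional `c(low_s, high_s)`; phases with duration in
#'   the closed interval qualify. `NULL` pools all phases of the label.
#' @param n_points grid size (default 30).
#' @return an object of class `normalized_profile` with elements `metric`,
#'   `label`, `grid` (`u_k = k/29`), `mean`, `sd`, `n_phases`.
#' @export
pool_profiles <- function(phases, metric, label = c("flexion", "extension"),
                          duration_filter = NULL, n_points = 30L) {
  label <- match.arg(label)
  labs <- vapply(phases, `[[`, character(1), "label")
  keep <- labs == label & vapply(phases, `[[`, logical(1), "pooling_ok")
  if (!is.null(duration_filter)) {
    stopifnot(length(duration_filter) == 2L)
    durs <- vapply(phases, `[[`, numeric(1), "duration_s")
    keep <- keep & durs >= duration_filter[1] & durs <= duration_filter[2]
  }
  sel <- phases[keep]
  if (length(sel) < 2L)
    stopf("need at least 2 qualifying '%s' phases (got %d)", label, length(sel))
  mat <- vapply(sel, resample_normalized, numeric(n_points), metric = metric,
                n_points = n_points)
  structure(list(metric = metric, label = label,
                 grid = seq(0, 1, length.out = n_points),
                 mean = rowMeans(mat),
                 sd = apply(mat, 1L, sd),
                 n_phases = length(sel)),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("<normalized_profile> %s, %s phase, %d phases pooled, %d points\n",
              x$metric, x$label, x$n_phases, length(x$grid)))
  cat(sprintf("  mean range: %.4g-%.4g\n", min(x$mean), max(x$mean)))
  invisible(x)
}

#' @export
plot.normalized_profile <- function(x, ylab = x$metric, ...) {
  ylim <- range(x$mean + x$sd, x$mean - x$sd)
  plot.default(x$grid, x$mean, type = "l", lwd = 2, ylim = ylim,
               xlab = "normalized duration", ylab = ylab,
               main = sprintf("%s (%s, n = %d)", x$metric, x$label, x$n_phases),
               ...)
  lines(x$grid, x$mean + x$sd, lty = 2)
  lines(x$grid, x$mean - x$sd, lty = 2)
  invisible(x)
}

#' Compare two normalized profiles
#'
#' Per-grid-point relative discrepancy
#' `|mean_a - mean_b| / max(|mean_b|, eps)` and its average over the grid
#' (profile `b` is the reference, e.g. a manual measurement).
#'
#' @param a,b `normalized_profile` objects with the same metric, label and
#'   grid.
#' @param eps floor for the reference magnitude (default 1e-8).
#' @return list with `per_point` (numeric vector) and `summary` (mean over
#'   grid points).
#' @export
compare_profiles <- function(a, b, eps = 1e-8) {
  stopifnot(inherits(a, "normalized_profile"), inherits(b, "normalized_profile"))
  if (a$metric != b$metric) stopf("profiles measure different metrics")
  if (a$label != b$label) stopf("profiles belong to different phase labels")
  if (length(a$grid) != length(b$grid) || any(abs(a$grid - b$grid) > 1e-12))
    stopf("profiles use different grids")
  per_point <- abs(a$mean - b$mean) / pmax(abs(b$mean), eps)
  list(per_point = per_point, summary = mean(per_point))
}
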