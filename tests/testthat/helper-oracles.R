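# Independent oracles, deliberately written as naive brute force so they share
# no code path with the implementation.

# zeroth moment by explicit double loop
brute_csa <- function(m) {
  s <- 0L
  for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) s <- s + m[r, cc]
  s
}

# first moments by explicit double loop; 0-based coordinates
brute_centroid <- function(m) {
  sx <- 0; sy <- 0; s <- 0
  for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) {
    f <- m[r, cc]
    sx <- sx + (cc - 1) * f
    sy <- sy + (r - 1) * f
    s <- s + f
  }
  c(cx = sx / s, cy = sy / s)
}

# set-count IoU on pixel index sets
brute_iou <- function(a, b) {
  A <- which(a == 1L); B <- which(b == 1L)
  if (length(A) == 0L && length(B) == 0L) return(1)
  length(intersect(A, B)) / length(union(A, B))
}

# second-implementation perimeter oracle: ordered outer contour from
# EBImage::ocontour, closed-polygon arc length through pixel centres
ocontour_perimeter <- function(m) {
  oc <- EBImage::ocontour(EBImage::bwlabel(m))[[1]]
  if (nrow(oc) < 2L) return(0)
  d <- diff(rbind(oc, oc[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# independent linear interpolation at query points u (data at x, values v)
interp_oracle <- function(x, v, u) {
  out <- numeric(length(u))
  for (i in seq_along(u)) {
    ui <- u[i]
    if (ui <= x[1]) { out[i] <- v[1]; next }
    if (ui >= x[length(x)]) { out[i] <- v[length(v)]; next }
    j <- max(which(x <= ui))
    if (x[j] == ui) { out[i] <- v[j]; next }
    w <- (ui - x[j]) / (x[j + 1] - x[j])
    out[i] <- (1 - w) * v[j] + w * v[j + 1]
  }
  out
}
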