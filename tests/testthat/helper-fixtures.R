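# shared fixtures, built in code

disc_mask <- function(r, h = ceiling(2 * r + 8), w = h,
                      cx = (w - 1) / 2 + 0.5, cy = (h - 1) / 2 + 0.5) {
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  matrix(as.integer((x - cx)^2 + (y - cy)^2 <= r^2), h, w)
}

# filled equilateral triangle, flat bottom, side s
triangle_mask <- function(s, pad = 8) {
  hgt <- s * sqrt(3) / 2
  h <- ceiling(hgt) + 2 * pad; w <- ceiling(s) + 2 * pad
  ax <- pad; ay <- pad + hgt          # bottom-left vertex
  bx <- pad + s; by <- ay             # bottom-right
  cx <- pad + s / 2; cy <- pad        # apex
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  s1 <- (bx - ax) * (y - ay) - (by - ay) * (x - ax)
  s2 <- (cx - bx) * (y - by) - (cy - by) * (x - bx)
  s3 <- (ax - cx) * (y - cy) - (ay - cy) * (x - cx)
  matrix(as.integer((s1 <= 0 & s2 <= 0 & s3 <= 0) | (s1 >= 0 & s2 >= 0 & s3 >= 0)),
         h, w)
}

# fat random blob: union of a few overlapping discs (single 8-connected
# component, no thin necks)
blob_mask <- function(h = 48, w = 48, n_discs = 3) {
  m <- matrix(0L, h, w)
  c0 <- c(runif(1, h / 3, 2 * h / 3), runif(1, w / 3, 2 * w / 3))
  for (b in seq_len(n_discs)) {
    r <- runif(1, 4, 8)
    cc <- c0 + runif(2, -5, 5)
    m <- m | disc_mask(r, h, w, cx = cc[2], cy = cc[1])
  }
  matrix(as.integer(m), h, w)
}

# the same continuous blob (union of discs) rasterized at integer scale k:
# used for scale-covariance checks, where block replication of pixels would
# corrugate the boundary instead of scaling it
scaled_blob <- function(seed, k = 1L, base = 90L) {
  set.seed(seed)
  nd <- sample(3:4, 1)
  centers <- cbind(runif(nd, 0.42 * base, 0.58 * base),
                   runif(nd, 0.42 * base, 0.58 * base))
  radii <- runif(nd, 16, 22)
  hh <- base * k
  x <- matrix(rep(0:(hh - 1), each = hh), hh, hh)
  y <- matrix(rep(0:(hh - 1), times = hh), hh, hh)
  m <- matrix(0L, hh, hh)
  for (i in seq_len(nd))
    m <- m | ((x - centers[i, 1] * k)^2 + (y - centers[i, 2] * k)^2 <= (radii[i] * k)^2)
  matrix(as.integer(m), hh, hh)
}

# random scattered binary mask (possibly many components / isolated pixels)
rand_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# minimal metrics records for phase-analysis tests
make_records <- function(time_s, cx_cm, cy_cm = 0, csa_cm2 = 0.12,
                         circularity = 0.6, valid = TRUE) {
  n <- length(time_s)
  data.frame(frame_index = seq_len(n) - 1L, time_s = time_s,
             csa_px = rep_len(csa_cm2, n) * 1e4, csa_cm2 = rep_len(csa_cm2, n),
             cx_px = rep_len(cx_cm, n) * 100, cy_px = rep_len(cy_cm, n) * 100,
             cx_cm = rep_len(cx_cm, n), cy_cm = rep_len(cy_cm, n),
             perimeter_px = 130, perimeter_cm = 1.3,
             circularity = rep_len(circularity, n),
             step_displacement_cm = NA_real_, valid = rep_len(valid, n))
}

# hand-built phase object for histogram / resampling tests
make_phase <- function(time_s, values, label = "flexion",
                       metric = "csa_cm2", valid = NULL) {
  n <- length(time_s)
  if (is.null(valid)) valid <- rep(TRUE, n)
  tr <- data.frame(frame_index = seq_len(n) - 1L, time_s = time_s, valid = valid)
  tr[[metric]] <- values
  structure(list(label = label, start = 1L, end = n,
                 frame_start = 0L, frame_end = n - 1L,
                 duration_s = time_s[n] - time_s[1], n_frames = n,
                 trace = tr, pooling_ok = TRUE),
            class = "nerve_phase")
}

fake_phase <- function(duration_s, label = "flexion") {
  make_phase(c(0, duration_s), c(1, 1), label = label)
}

# memoized default simulation shared across test files
.fixture_env <- new.env(parent = emptyenv())
shared_sim <- function() {
  if (is.null(.fixture_env$sim)) .fixture_env$sim <- generate_truth(sim_spec(seed = 7))
  .fixture_env$sim
}
shared_metrics <- function() {
  if (is.null(.fixture_env$met))
    .fixture_env$met <- sequence_metrics(shared_sim()$sequence)
  .fixture_env$met
}
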