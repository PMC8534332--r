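# --- star-convex shape family: r(theta) = r0 * (1 + m * cos(3 * theta)) ----
# Three-fold symmetry interpolates a circle (m = 0) toward a rounded triangle;
# the region centroid stays at the centre exactly, and the analytic area is
# A = pi * r0^2 * (1 + m^2 / 2).

# analytic circularity of the continuous shape as a function of m (r0 cancels)
shape_circularity <- function(m, n_grid = 2048L) {
  th <- seq(0, 2 * pi, length.out = n_grid)
  r <- 1 + m * cos(3 * th)
  rp <- -3 * m * sin(3 * th)
  f <- sqrt(r^2 + rp^2)
  per <- sum((f[-1] + f[-n_grid]) / 2 * diff(th))  # trapezoid rule
  area <- pi * (1 + m^2 / 2)
  4 * pi * area / per^2
}

# invert circularity -> m on a precomputed monotone grid
shape_m_table <- function() {
  ms <- seq(0, 0.55, by = 0.0025)
  circ <- vapply(ms, shape_circularity, numeric(1))
  list(m = ms, circ = circ, circ_min = min(circ))
}

solve_shape <- function(csa_px, circ_target, tab) {
  if (circ_target > 1 || circ_target < tab$circ_min)
    stopf("shape family cannot reach circularity %.3f (achievable range [%.2f, 1])",
          circ_target, tab$circ_min)
  m <- approx(tab$circ, tab$m, xout = circ_target)$y
  r0 <- sqrt(csa_px / (pi * (1 + m^2 / 2)))
  c(r0 = r0, m = m)
}

# rasterize the shape: pixel centres at 0-based (x, y); foreground where the
# distance to (cx, cy) is at most r(theta)
raster_shape <- function(h, w, cx, cy, r0, m, phi) {
  x <- matrix(rep(0:(w - 1L), each = h), h, w)
  y <- matrix(rep(0:(h - 1L), times = w), h, w)
  dx <- x - cx; dy <- y - cy
  th <- atan2(dy, dx)
  rr <- sqrt(dx^2 + dy^2)
  matrix(as.integer(rr <= r0 * (1 + m * cos(3 * (th - phi)))), h, w)
}

#' Simulation specification for a synthetic nerve mask sequence
#'
#' Defaults emulate the study conditions of dynamic ultrasound of the median
#' nerve during finger motion: acquisition at 38 frames/s sampled every 4th
#' frame, about 5 flexion/extension cycles of roughly 0.68 s / 0.48 s modal
#' duration, a nerve of 0.12 cm2 cross-section whose area shrinks ~12 percent
#' at peak flexion, a centroid excursion of ~0.10 cm (1 mm) predominantly
#' along -x (toward the ulnar side), and a circularity near 0.62 (between a
#' circle at 1 and an equilateral triangle at ~0.6).
#'
#' @param image_size integer `c(h, w)` of the mask grid (default 128 x 128).
#' @param px_per_cm pixels per centimetre (default 100).
#' @param fps,frame_step acquisition rate and sampling step (defaults 38, 4).
#' @param n_cycles number of flexion/extension cycles (default 5).
#' @param flexion_mean_s,flexion_sd_s,extension_mean_s,extension_sd_s means
#'   and SDs of the truncated-normal phase-duration distributions (defaults
#'   0.68/0.08 s and 0.48/0.04 s).
#' @param duration_min_s truncation floor for both distributions (default 0.3).
#' @param base_csa_cm2 cross-sectional area at the flexion start (default 0.12).
#' @param csa_amplitude signed fractional area change at peak flexion
#'   (default -0.12, a 12 percent shrink; positive values model swelling).
#' @param centroid_excursion_cm centroid excursion along -x at peak flexion
#'   (default 0.10 cm).
#' @param y_excursion_cm centroid excursion along +y at peak flexion
#'   (default 0.02 cm).
#' @param base_circularity circularity at flexion start (default 0.62).
#' @param circularity_amplitude circularity drop at peak flexion (default
#'   0.03; the nerve gets less circular as it deforms. Negative values flip
#'   the direction).
#' @param seed integer seed; generation is a pure function of the spec.
#' @return an object of class `sim_spec`.
#' @export
sim_spec <- function(image_size = c(128L, 128L), px_per_cm = 100, fps = 38,
                     frame_step = 4L, n_cycles = 5L,
                     flexion_mean_s = 0.68, flexion_sd_s = 0.08,
                     extension_mean_s = 0.48, extension_sd_s = 0.04,
                     duration_min_s = 0.3,
                     base_csa_cm2 = 0.12, csa_amplitude = -0.12,
                     centroid_excursion_cm = 0.10, y_excursion_cm = 0.02,
                     base_circularity = 0.62, circularity_amplitude = 0.03,
                     seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16))
  if (!is_number(base_csa_cm2) || base_csa_cm2 <= 0) stopf("base_csa_cm2 must be > 0")
  if (abs(csa_amplitude) >= 1) stopf("|csa_amplitude| must be < 1")
  if (duration_min_s <= 0) stopf("duration_min_s must be > 0")
  if (!is_count(n_cycles, 1L)) stopf("n_cycles must be a positive integer")
  structure(list(image_size = as.integer(image_size), px_per_cm = px_per_cm,
                 fps = fps, frame_step = as.integer(frame_step),
                 n_cycles = as.integer(n_cycles),
                 flexion_mean_s = flexion_mean_s, flexion_sd_s = flexion_sd_s,
                 extension_mean_s = extension_mean_s,
                 extension_sd_s = extension_sd_s,
                 duration_min_s = duration_min_s,
                 base_csa_cm2 = base_csa_cm2, csa_amplitude = csa_amplitude,
                 centroid_excursion_cm = centroid_excursion_cm,
                 y_excursion_cm = y_excursion_cm,
                 base_circularity = base_circularity,
                 circularity_amplitude = circularity_amplitude,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(paste0("<sim_spec> %dx%d px, %g px/cm, dt = %.4f s, %d cycles, ",
                     "CSA %.3g cm2 (amplitude %+.2f), excursion %.2f cm, ",
                     "circularity %.2f, seed %d\n"),
              x$image_size[1], x$image_size[2], x$px_per_cm,
              x$frame_step / x$fps, x$n_cycles, x$base_csa_cm2,
              x$csa_amplitude, x$centroid_excursion_cm, x$base_circularity,
              x$seed))
  invisible(x)
}

#' Degradation specification for synthetic predicted masks
#'
#' Emulates the failure conditions seen in model inference on dynamic
#' ultrasound: boundary jitter (imprecise contours), occasional frames with
#' elevated jitter (blurred-appearance frames), distractor blobs (adjacent
#' hypoechoic structures mistaken for the nerve; always strictly smaller than
#' the nerve and at least 3 px away), region splits, and scored instance
#' candidates.
#'
#' @param boundary_jitter_px peak amplitude of the smooth radial boundary
#'   perturbation, in pixels (default 2).
#' @param distractor_prob per-frame probability of a distractor blob in the
#'   semantic output (default 0.1).
#' @param distractor_area_frac distractor area as a fraction of the nerve
#'   area; must be < 1 (default 0.15).
#' @param split_prob per-frame probability that the semantic nerve mask is cut
#'   in two (default 0.02).
#' @param blur_frames_frac fraction of frames with tripled jitter (default 0.05).
#' @param candidate_count instance candidates per frame: the nerve plus
#'   `candidate_count - 1` distractor candidates (default 3).
#' @param score_noise_sd SD of the Gaussian noise added to the true-IoU
#'   candidate scores, clipped to `[0, 1]` (default 0.05).
#' @param seed integer seed.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(boundary_jitter_px = 2, distractor_prob = 0.1,
                       distractor_area_frac = 0.15, split_prob = 0.02,
                       blur_frames_frac = 0.05, candidate_count = 3L,
                       score_noise_sd = 0.05, seed = 1L) {
  if (distractor_area_frac >= 1 || distractor_area_frac < 0)
    stopf("distractor_area_frac must be in [0, 1): the distractor is strictly smaller than the nerve")
  if (!is_count(candidate_count, 1L)) stopf("candidate_count must be >= 1")
  stopifnot(boundary_jitter_px >= 0, distractor_prob >= 0, distractor_prob <= 1,
            split_prob >= 0, split_prob <= 1, blur_frames_frac >= 0,
            blur_frames_frac <= 1, score_noise_sd >= 0)
  structure(list(boundary_jitter_px = boundary_jitter_px,
                 distractor_prob = distractor_prob,
                 distractor_area_frac = distractor_area_frac,
                 split_prob = split_prob, blur_frames_frac = blur_frames_frac,
                 candidate_count = as.integer(candidate_count),
                 score_noise_sd = score_noise_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

rtruncnorm1 <- function(mean, sd, min) {
  repeat {
    x <- rnorm(1L, mean, sd)
    if (x >= min) return(x)
  }
}

#' Generate a synthetic ground-truth nerve mask sequence
#'
#' Renders one star-convex nerve cross-section per frame from the
#' circle-to-rounded-triangle family `r(theta) = r0 (1 + m cos 3 theta)`,
#' with `(r0, m)` solved per frame to hit the programmed area and
#' circularity. A piecewise-linear activation `s(t)` ramps 0 to 1 over each
#' flexion phase and back over extension; per frame,
#' `CSA(t) = base * (1 + amplitude * s(t))`, the centroid moves from its rest
#' position by `excursion * s(t)` along -x (and `y_excursion * s(t)` along
#' +y), and circularity is `base - circularity_amplitude * s(t)`. Phase
#' durations are drawn from truncated normal distributions. Output is a pure
#' function of the spec (including its seed).
#'
#' @param spec a [sim_spec()].
#' @return list of class `sim_truth` with elements
#'   * `sequence`: the ground-truth [mask_sequence()];
#'   * `truth`: per-frame table of programmed values (`frame_index`, `time_s`,
#'     `phase_id`, `phase_label`, `s`, `csa_px_true`, `csa_cm2_true`,
#'     `cx_px_true`, `cy_px_true`, `circularity_true`);
#'   * `phases`: programmed phase table (`phase_id`, `label`, `start_s`,
#'     `end_s`, `duration_s`, `boundary_frame` = sampled frame nearest the
#'     phase start).
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  px <- spec$px_per_cm
  dt <- spec$frame_step / spec$fps
  tab <- shape_m_table()

  drawn <- with_seed(spec$seed, {
    durs <- numeric(2L * spec$n_cycles)
    labs <- character(2L * spec$n_cycles)
    for (i in seq_len(spec$n_cycles)) {
      durs[2L * i - 1L] <- rtruncnorm1(spec$flexion_mean_s, spec$flexion_sd_s,
                                       spec$duration_min_s)
      durs[2L * i] <- rtruncnorm1(spec$extension_mean_s, spec$extension_sd_s,
                                  spec$duration_min_s)
      labs[2L * i - 1L] <- "flexion"
      labs[2L * i] <- "extension"
    }
    list(durs = durs, labs = labs, phi = runif(1L, 0, 2 * pi / 3))
  })
  durs <- drawn$durs; labs <- drawn$labs; phi <- drawn$phi

  starts <- cumsum(c(0, durs))
  total <- starts[length(starts)]
  t_frames <- seq(0, total, by = dt)
  t_frames <- t_frames[t_frames <= total + 1e-12]
  n <- length(t_frames)

  # rest-position centroid, placed so the full excursion stays inside the grid
  ex_px <- spec$centroid_excursion_cm * px
  ey_px <- spec$y_excursion_cm * px
  cx0 <- (w - 1) / 2 + ex_px / 2
  cy0 <- (h - 1) / 2 - ey_px / 2

  pid <- pmin(findInterval(t_frames, starts, left.open = FALSE),
              length(durs))
  s <- numeric(n)
  for (i in seq_len(n)) {
    p <- pid[i]
    frac <- (t_frames[i] - starts[p]) / durs[p]
    frac <- min(max(frac, 0), 1)
    s[i] <- if (labs[p] == "flexion") frac else 1 - frac
  }

  csa_px_true <- spec$base_csa_cm2 * (1 + spec$csa_amplitude * s) * px^2
  circ_true <- spec$base_circularity - spec$circularity_amplitude * s
  cx_true <- cx0 - ex_px * s
  cy_true <- cy0 + ey_px * s

  frames <- vector("list", n)
  for (i in seq_len(n)) {
    sh <- solve_shape(csa_px_true[i], circ_true[i], tab)
    rmax <- sh[["r0"]] * (1 + abs(sh[["m"]]))
    if (cx_true[i] - rmax < 0 || cx_true[i] + rmax > w - 1 ||
        cy_true[i] - rmax < 0 || cy_true[i] + rmax > h - 1)
      stopf("shape leaves the %dx%d grid at frame %d; enlarge image_size", h, w, i - 1L)
    frames[[i]] <- mask_frame(raster_shape(h, w, cx_true[i], cy_true[i],
                                           sh[["r0"]], sh[["m"]], phi),
                              frame_index = i - 1L)
  }
  meta <- sequence_meta(px_per_cm = px, fps = spec$fps,
                        frame_step = spec$frame_step,
                        axis_labels = c(x = "scaphoid (radial)", y = "palmar"))
  truth <- data.frame(frame_index = seq_len(n) - 1L, time_s = t_frames,
                      phase_id = pid, phase_label = labs[pid], s = s,
                      csa_px_true = csa_px_true,
                      csa_cm2_true = csa_px_true / px^2,
                      cx_px_true = cx_true, cy_px_true = cy_true,
                      circularity_true = circ_true)
  phases <- data.frame(phase_id = seq_along(durs), label = labs,
                       start_s = starts[-length(starts)],
                       end_s = starts[-1], duration_s = durs,
                       boundary_frame = as.integer(round(starts[-length(starts)] / dt)))
  structure(list(sequence = mask_sequence(frames, meta), truth = truth,
                 phases = phases, spec = spec),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> %d frames, %d phases, total %.2f s\n",
              nrow(x$truth), nrow(x$phases), max(x$phases$end_s)))
  invisible(x)
}

# smooth periodic radial perturbation with peak amplitude `amp`
radial_noise_field <- function(amp) {
  coef <- rnorm(6L)
  f <- function(th) {
    coef[1] * cos(th) + coef[2] * sin(th) +
      coef[3] * cos(2 * th) + coef[4] * sin(2 * th) +
      coef[5] * cos(3 * th) + coef[6] * sin(3 * th)
  }
  peak <- max(abs(f(seq(0, 2 * pi, length.out = 721L))))
  if (peak == 0) return(function(th) 0 * th)
  function(th) amp * f(th) / peak
}

# perturb the mask boundary radially by delta(theta) around the mask centroid:
# the signed distance to the boundary is shifted locally by delta
jitter_mask <- function(m, delta_fun) {
  d_in <- EBImage::distmap(m)
  d_out <- EBImage::distmap(1L - m)
  signed <- d_in - d_out
  cen <- compute_centroid(m)
  x <- col(m) - 1L; y <- row(m) - 1L
  th <- atan2(y - cen[["cy"]], x - cen[["cx"]])
  matrix(as.integer(signed >= 0.5 - delta_fun(th)), nrow(m), ncol(m))
}

# cut the mask with a 2 px wide band through its centroid at a random angle
split_mask <- function(m, angle) {
  cen <- compute_centroid(m)
  x <- col(m) - 1L; y <- row(m) - 1L
  band <- abs((x - cen[["cx"]]) * cos(angle) + (y - cen[["cy"]]) * sin(angle)) < 1
  out <- m
  out[band] <- 0L
  out
}

# disc of given area placed >= 3 px away from the nerve; NULL when no
# placement is found
place_distractor <- function(nerve, area_px, max_tries = 60L) {
  h <- nrow(nerve); w <- ncol(nerve)
  rd <- sqrt(area_px / pi)
  dmap <- EBImage::distmap(1L - nerve)  # distance to the nearest nerve pixel
  for (k in seq_len(max_tries)) {
    cx <- runif(1L, rd + 1, w - rd - 2)
    cy <- runif(1L, rd + 1, h - rd - 2)
    if (dmap[round(cy) + 1L, round(cx) + 1L] >= rd + 3 + 1) {
      x <- col(nerve) - 1L; y <- row(nerve) - 1L
      return(matrix(as.integer((x - cx)^2 + (y - cy)^2 <= rd^2), h, w))
    }
  }
  NULL
}

#' Degrade a ground-truth sequence into synthetic model predictions
#'
#' Produces (a) a semantic-style predicted sequence — the nerve mask with a
#' smooth radial boundary jitter, optionally cut in two (`split_prob`) and
#' optionally accompanied by a disjoint distractor blob (`distractor_prob`,
#' placed at least 3 px from the nerve and strictly smaller than it) — and
#' (b) per-frame instance candidate sets holding the jittered nerve plus
#' `candidate_count - 1` distractor candidates, scored by their true IoU
#' against the ground truth plus Gaussian noise, clipped to `[0, 1]`. A
#' fraction `blur_frames_frac` of frames receives tripled jitter, emulating
#' motion-blurred frames. Deterministic given `(truth, noise)`.
#'
#' @param truth a `sim_truth` from [generate_truth()] or a [mask_sequence()].
#' @param noise a [noise_spec()].
#' @return list with `semantic` (a [mask_sequence()]) and `candidates` (list
#'   of [candidate_set()], one per frame).
#' @export
degrade <- function(truth, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  seq_in <- if (inherits(truth, "sim_truth")) truth$sequence else truth
  stopifnot(inherits(seq_in, "mask_sequence"))
  n <- length(seq_in$frames)
  with_seed(noise$seed, {
    blurred <- logical(n)
    n_blur <- floor(noise$blur_frames_frac * n)
    if (n_blur > 0L) blurred[sample.int(n, n_blur)] <- TRUE
    sem_frames <- vector("list", n)
    cand_sets <- vector("list", n)
    for (i in seq_len(n)) {
      g <- as_pixel_matrix(seq_in$frames[[i]])
      fi <- frame_index_of(seq_in$frames[[i]])
      amp <- noise$boundary_jitter_px * if (blurred[i]) 3 else 1
      delta <- radial_noise_field(amp)
      nerve <- if (amp > 0) jitter_mask(g, delta) else g
      sem <- nerve
      if (runif(1L) < noise$split_prob) sem <- split_mask(sem, runif(1L, 0, pi))
      if (runif(1L) < noise$distractor_prob) {
        blob <- place_distractor(nerve, noise$distractor_area_frac * sum(nerve))
        if (!is.null(blob)) sem <- matrix(as.integer(sem | blob), nrow(g), ncol(g))
      }
      sem_frames[[i]] <- mask_frame(sem, fi)

      cands <- vector("list", noise$candidate_count)
      cands[[1L]] <- nerve
      if (noise$candidate_count > 1L) {
        for (k in 2:noise$candidate_count) {
          blob <- place_distractor(nerve, noise$distractor_area_frac * sum(nerve))
          cands[[k]] <- if (is.null(blob)) matrix(0L, nrow(g), ncol(g)) else blob
        }
      }
      scores <- vapply(cands, compute_iou, numeric(1), b = g)
      if (noise$score_noise_sd > 0)
        scores <- scores + rnorm(length(scores), 0, noise$score_noise_sd)
      scores <- pmin(pmax(scores, 0), 1)
      cand_sets[[i]] <- candidate_set(fi, cands, scores, dim = dim(g))
    }
    list(semantic = mask_sequence(sem_frames, seq_in$meta),
         candidates = cand_sets)
  })
}
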