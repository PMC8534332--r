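dt <- 4 / 38

test_that("a constant centroid trace yields no phases", {
  rec <- make_records(time_s = (0:30) * dt, cx_cm = rep(0.5, 31))
  expect_warning(ph <- segment_phases(rec), "no phases")
  expect_length(ph, 0L)
})

test_that("a clean triangular centroid waveform yields alternating phases at its vertices", {
  # 4 full cycles flanked by partial limbs so all 9 delimiting vertices are interior
  verts <- c(3L, 9L, 14L, 20L, 25L, 31L, 36L, 42L, 47L)
  n <- 51L
  cx <- numeric(n)
  lvl <- c(0.55, 0.45)  # cx falls during flexion, rises during extension
  knots_x <- c(0L, verts, n - 1L)
  knots_y <- c(0.5, rep(lvl, length.out = length(verts)), 0.5)
  cx <- approx(knots_x, knots_y, xout = 0:(n - 1L))$y
  rec <- make_records(time_s = (0:(n - 1L)) * dt, cx_cm = cx)
  ph <- segment_phases(rec)
  expect_length(ph, 8L)
  labs <- vapply(ph, `[[`, character(1), "label")
  expect_true(all(labs[-1] != labs[-length(labs)]))  # strict alternation
  expect_equal(labs[1], "flexion")  # first interior run has falling cx
  starts <- vapply(ph, `[[`, integer(1), "frame_start")
  ends <- vapply(ph, `[[`, integer(1), "frame_end")
  expect_true(all(abs(starts - verts[-length(verts)]) <= 1))
  expect_true(all(abs(ends - verts[-1]) <= 1))
  # duration invariant: (n_frames - 1) * dt
  for (p in ph) expect_equal(p$duration_s, (p$n_frames - 1L) * dt)
})

test_that("annotated mode returns the phases exactly as annotated", {
  rec <- make_records(time_s = (0:20) * dt, cx_cm = sin((0:20) / 3))
  ann <- phase_annotation(c(0L, 7L, 12L), c(7L, 12L, 19L),
                          c("flexion", "extension", "flexion"))
  ph <- segment_phases(rec, mode = "annotated", annotation = ann)
  expect_length(ph, 3L)
  expect_equal(vapply(ph, `[[`, integer(1), "frame_start"), c(0L, 7L, 12L))
  expect_equal(vapply(ph, `[[`, integer(1), "frame_end"), c(7L, 12L, 19L))
  expect_equal(vapply(ph, `[[`, character(1), "label"),
               c("flexion", "extension", "flexion"))
  bad <- phase_annotation(0L, 25L, "flexion")
  expect_error(segment_phases(rec, mode = "annotated", annotation = bad),
               "absent")
})

test_that("centroid offset is measured from the enclosing flexion start", {
  # flexion 0->10 (cx falls 0.1), extension 10->20 (cx returns)
  cx <- c(seq(0.6, 0.5, length.out = 11), seq(0.5, 0.6, length.out = 11)[-1])
  rec <- make_records(time_s = (0:20) * dt, cx_cm = cx, cy_cm = 0)
  ann <- phase_annotation(c(0L, 10L), c(10L, 20L), c("flexion", "extension"))
  ph <- segment_phases(rec, mode = "annotated", annotation = ann)
  expect_equal(ph[[1]]$trace$centroid_offset_cm[1], 0)
  expect_equal(max(ph[[1]]$trace$centroid_offset_cm), 0.1)
  # the extension phase measures offsets from the flexion start too
  expect_equal(ph[[2]]$trace$centroid_offset_cm[1], 0.1)
  expect_equal(ph[[2]]$trace$centroid_offset_cm[11], 0, tolerance = 1e-12)
})

test_that("duration histogram thresholds pick the modal run", {
  # identical durations: one occupied bin, D90 = D50 = its edges
  ph <- replicate(5, fake_phase(0.53), simplify = FALSE)
  h <- duration_histogram(ph, "flexion")
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$d90_range_s, c(0.51, 0.54))
  expect_equal(h$d50_range_s, c(0.51, 0.54))
  # counts [1, 10, 9, 2] in consecutive bins: thresholds 9 and 5 keep the
  # run of the two central bins
  durs <- c(rep(0.43, 1), rep(0.46, 10), rep(0.49, 9), rep(0.52, 2))
  ph2 <- lapply(durs, fake_phase)
  h2 <- duration_histogram(ph2, "flexion")
  expect_equal(h2$counts[h2$counts > 0], c(1, 10, 9, 2))
  expect_equal(h2$d90_range_s, c(0.45, 0.51))
  expect_equal(h2$d50_range_s, c(0.45, 0.51))
  expect_error(duration_histogram(ph2, "extension"), "no phases")
})

test_that("D90 is contained in D50 and both contain the mode, for random inputs", {
  set.seed(41)
  for (i in 1:20) {
    durs <- abs(rnorm(sample(3:40, 1), mean = 0.6, sd = 0.2)) + 0.05
    h <- duration_histogram(lapply(durs, fake_phase), "flexion")
    expect_gte(h$d90_range_s[1], h$d50_range_s[1])
    expect_lte(h$d90_range_s[2], h$d50_range_s[2])
    mode_lo <- h$bin_edges[h$mode_bin]
    expect_gte(mode_lo, h$d90_range_s[1] - 1e-12)
    expect_lte(h$bin_edges[h$mode_bin + 1L], h$d90_range_s[2] + 1e-12)
  }
})

test_that("normalized resampling is exact on constant and affine traces", {
  t <- (0:16) * dt
  expect_equal(resample_normalized(make_phase(t, rep(7, 17)), "csa_cm2"),
               rep(7, 30))
  ramp <- resample_normalized(make_phase(t, seq(0, 1, length.out = 17)), "csa_cm2")
  expect_equal(ramp, seq(0, 1, length.out = 30), tolerance = 1e-12)
  # idempotence: a trace already sampled at u_k is reproduced exactly
  u <- seq(0, 1, length.out = 30)
  v <- sin(3 * u) + u
  expect_equal(resample_normalized(make_phase(u, v), "csa_cm2"), v,
               tolerance = 1e-12)
})

test_that("resampling matches an independent interpolation oracle", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    t <- cumsum(runif(n, 0.5, 1.5))
    v <- rnorm(n)
    got <- resample_normalized(make_phase(t, v), "csa_cm2")
    u <- (t - t[1]) / (t[n] - t[1])
    expect_equal(got, interp_oracle(u, v, seq(0, 1, length.out = 30)),
                 tolerance = 1e-12)
    expect_identical(c(got[1], got[30]), c(v[1], v[n]))
  }
})

test_that("short gaps are bridged linearly; long gaps disqualify the phase", {
  t <- (0:10) * dt
  v <- seq(10, 20, length.out = 11)
  v[5:6] <- NA  # 2 consecutive invalid frames: bridged
  got <- resample_normalized(make_phase(t, v), "csa_cm2")
  expect_equal(got, seq(10, 20, length.out = 30), tolerance = 1e-12)
  v[5:7] <- NA  # 3 consecutive: disqualified
  expect_error(resample_normalized(make_phase(t, v), "csa_cm2"), "consecutive")
  v2 <- seq(10, 20, length.out = 11); v2[1] <- NA
  expect_error(resample_normalized(make_phase(t, v2), "csa_cm2"), "boundary")
})

test_that("pooled profiles report per-point mean and n-1 standard deviation", {
  t <- (0:9) * dt
  p4 <- make_phase(t, rep(4, 10))
  p8 <- make_phase(t, rep(8, 10))
  prof <- pool_profiles(list(p4, p8), "csa_cm2", "flexion")
  expect_length(prof$grid, 30L)
  expect_equal(prof$grid[c(1, 30)], c(0, 1))
  expect_equal(prof$mean, rep(6, 30))
  expect_equal(prof$sd, rep(2 * sqrt(2), 30))
  expect_equal(prof$n_phases, 2L)
  # identical phases: sd 0, mean = the common trace
  prof2 <- pool_profiles(list(p4, make_phase(t, rep(4, 10))), "csa_cm2", "flexion")
  expect_equal(prof2$sd, rep(0, 30))
  expect_equal(prof2$mean, rep(4, 30))
  # duration filter: too few qualifying phases is an error
  expect_error(pool_profiles(list(p4, p8), "csa_cm2", "flexion",
                             duration_filter = c(10, 20)), "qualifying")
})

test_that("profile comparison reports relative discrepancy against the reference", {
  t <- (0:9) * dt
  a <- pool_profiles(list(make_phase(t, seq(2, 3, length.out = 10)),
                          make_phase(t, seq(2, 3, length.out = 10))),
                     "csa_cm2", "flexion")
  expect_equal(compare_profiles(a, a)$summary, 0)
  b <- a
  b$mean <- 1.10 * a$mean
  cmp <- compare_profiles(a, b)
  expect_equal(cmp$summary, 0.1 / 1.1, tolerance = 1e-12)
  expect_length(cmp$per_point, 30L)
  wrong <- a; wrong$label <- "extension"
  expect_error(compare_profiles(a, wrong), "label")
})
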