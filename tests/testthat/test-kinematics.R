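# Track smoothing, cylindrical mapping, binning, contour fitting and shape
# metrics.

make_circle_points <- function(m, r = 10, center = c(0, 0, 0)) {
  th <- 2 * pi * (0:(m - 1)) / m
  list(P = cbind(center[1L] + r * cos(th), center[2L] + r * sin(th),
                 center[3L] + 0 * th),
       th = th)
}

test_that("EMA smoothing follows the stated recursion", {
  # constant track is unchanged
  tr <- tibble::tibble(track_id = rep(1:3, each = 5),
                       timepoint = rep(1:5, 3),
                       x_um = rep(c(1, 2, 3), each = 5), y_um = 0, z_um = 0)
  expect_equal(ema_smooth_tracks(tr)$x_um, tr$x_um)
  # unit step: value n steps after the step is 1 - (1-alpha)^(n+1)
  tr2 <- tibble::tibble(track_id = rep(1:3, each = 30),
                        timepoint = rep(1:30, 3),
                        x_um = rep(c(rep(0, 9), rep(1, 21)), 3),
                        y_um = 0, z_um = 0)
  sm <- ema_smooth_tracks(tr2, window = 10)
  alpha <- 2 / 11
  one <- sm[sm$track_id == 1L, ]
  for (n in c(0, 3, 10)) {
    expect_equal(one$x_um[10 + n], 1 - (1 - alpha)^(n + 1),
                 tolerance = 1e-12)
  }
  # smoothing commutes with rigid translation
  tr3 <- tr2
  tr3$x_um <- tr3$x_um + 5; tr3$y_um <- tr3$y_um - 2
  sm3 <- ema_smooth_tracks(tr3, window = 10)
  expect_equal(sm3$x_um, sm$x_um + 5, tolerance = 1e-12)
  expect_equal(sm3$y_um, sm$y_um - 2, tolerance = 1e-12)
})

test_that("incomplete tracks are rejected", {
  tr <- tibble::tibble(track_id = c(1, 1, 2), timepoint = c(1, 2, 1),
                       x_um = 0, y_um = 0, z_um = 0)
  expect_error(ema_smooth_tracks(tr), class = "morphoring_incomplete_track")
})

test_that("cylindrical mapping is degenerate-safe and rank-preserving", {
  expect_error(map_to_cylindrical(matrix(rnorm(6), 2L)),
               class = "morphoring_degenerate_configuration")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(map_to_cylindrical(line),
               class = "morphoring_degenerate_configuration")
  # ring band: w preserves the rank order of the axial coordinate
  set.seed(42)
  m <- 120
  th <- stats::runif(m, 0, 2 * pi)
  ax <- rep(seq(0, 4, length.out = 6), each = 20)
  P <- cbind(ax + stats::rnorm(m, 0, 0.05),
             (10 + 0.5 * ax) * cos(th), (10 + 0.5 * ax) * sin(th))
  colnames(P) <- c("x_um", "y_um", "z_um")
  cyl <- map_to_cylindrical(tibble::as_tibble(P))
  expect_gt(stats::cor(cyl$w, ax, method = "spearman"), 0.95)
  expect_true(all(cyl$phi > -pi & cyl$phi <= pi + 1e-12))
})

test_that("bin assignment is balanced on uniform w and errors when collapsed", {
  cyl <- tibble::tibble(track_id = 1:100, w = seq(0, 1, length.out = 100),
                        phi = 0)
  bins <- assign_bins(cyl, 5L)
  expect_equal(unname(table(bins)), rep(20L, 5L), ignore_attr = TRUE)
  cyl0 <- tibble::tibble(track_id = 1:10, w = rep(1, 10), phi = 0)
  expect_error(assign_bins(cyl0), class = "morphoring_empty_bin")
})

test_that("contour fitting recovers a 90-point circle to the documented bias", {
  cp <- make_circle_points(90)
  ct <- fit_closed_contour(cp$P, cp$th)
  expect_equal(nrow(ct), 500L)
  expect_equal(attr(ct, "length"), 2 * pi * 10, tolerance = 5e-3)
  # arclength spacing of the resampled points is uniform
  expect_lt(max(diff(ct$s)) / min(diff(ct$s)), 1 + 1e-6)
  # chord lengths are near-uniform for the circle
  P <- as.matrix(ct[, c("x", "y", "z")])
  seg <- sqrt(rowSums((P[c(2:500, 1L), ] - P)^2))
  expect_lt(max(seg) / min(seg), 1.01)
  cm <- contour_metrics(ct)
  expect_equal(unname(cm["A"]), pi * 100, tolerance = 0.01)
  expect_equal(unname(cm["R"]), 1 / (4 * pi), tolerance = 0.01)
})

test_that("the smoothing spline acts as a documented low-pass at 40 points", {
  cp <- make_circle_points(40)
  ct <- fit_closed_contour(cp$P, cp$th)
  shrink <- attr(ct, "length") / (2 * pi * 10) - 1
  expect_lt(shrink, 0)            # smoothing shortens the contour
  expect_gt(shrink, -0.08)        # by a few percent at this sampling
})

test_that("collinear points cannot close a loop", {
  P <- cbind(seq_len(40), 2 * seq_len(40), 0 * seq_len(40))
  expect_error(fit_closed_contour(P, seq_len(40)),
               class = "morphoring_loop_closure_failure")
  expect_error(fit_closed_contour(P[1:3, ], 1:3),
               class = "morphoring_too_few_points")
})

test_that("contour metrics match elliptic closed forms and scale invariance", {
  t <- seq(0, 2 * pi, length.out = 501)[-501]
  ell <- cbind(2 * cos(t), sin(t), 0 * t)
  cm <- contour_metrics(ell)
  # perimeter by independent quadrature
  P_or <- stats::integrate(function(u) sqrt(4 * sin(u)^2 + cos(u)^2),
                           0, 2 * pi, rel.tol = 1e-12)$value
  expect_equal(unname(cm["L"]), P_or, tolerance = 1e-4)
  expect_equal(unname(cm["A"]), 2 * pi, tolerance = 1e-3)
  expect_equal(unname(cm["R"]), 2 * pi / P_or^2, tolerance = 1e-3)
  cm3 <- contour_metrics(3 * ell)
  expect_equal(unname(cm3["R"]), unname(cm["R"]), tolerance = 1e-12)
})

test_that("axis extents match brute-force projections for rotated ellipses", {
  t <- seq(0, 2 * pi, length.out = 721)[-721]
  ell <- cbind(2 * cos(t), sin(t), 0 * t)
  ax <- axis_lengths(ell)
  expect_equal(unname(ax["f_y"]), 4, tolerance = 1e-4)
  expect_equal(unname(ax["f_x"]), 2, tolerance = 1e-4)
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- ell %*% t(Rz)
  axr <- axis_lengths(rot)
  expect_equal(unname(axr["f_y"]), diff(range(rot[, 1L])), tolerance = 1e-12)
  expect_equal(unname(axr["f_x"]), diff(range(rot[, 2L])), tolerance = 1e-12)
})

test_that("intercontour distances are exact for concentric circles", {
  mk <- function(r) {
    t <- seq(0, 2 * pi, length.out = 501)[-501]
    cbind(r * cos(t), r * sin(t), 0 * t)
  }
  d <- intercontour_distances(mk(8), mk(10), mk(12))
  expect_equal(unname(d["d_i"]), 2, tolerance = 1e-4)
  expect_equal(unname(d["d_o"]), 2, tolerance = 1e-4)
  d0 <- intercontour_distances(mk(10), mk(10), mk(10))
  expect_lt(max(abs(d0)), 1e-6)
  # normal-offset ellipses: mean distance equals the offset
  t <- seq(0, 2 * pi, length.out = 501)[-501]
  base <- cbind(2 * cos(t), sin(t), 0 * t)
  nx <- cos(t); ny <- 2 * sin(t); nn <- sqrt(nx^2 + ny^2)
  off <- cbind(2 * cos(t) + 0.15 * nx / nn, sin(t) + 0.15 * ny / nn, 0 * t)
  dd <- intercontour_distances(base, base, off)
  expect_equal(unname(dd["d_o"]), 0.15, tolerance = 0.01)
})

test_that("the sagittal position coordinate reduces to known limits", {
  expect_equal(elliptic_arc(0, 0.92), 0)
  th <- seq(-1, 1.4, by = 0.4)
  expect_equal(elliptic_arc(th, 0), th, tolerance = 1e-12)
  # quadrature oracle at the paper's eccentricity
  orc <- stats::integrate(function(u) sqrt(1 - 0.92^2 * sin(u)^2), 0,
                          pi / 2, rel.tol = 1e-12)$value
  expect_equal(elliptic_arc(pi / 2, 0.92), orc, tolerance = 1e-10)
})

test_that("normalized metrics equal one at the reference timepoint", {
  m <- tibble::tibble(
    bin = rep(1:2, each = 4), timepoint = rep(1:4, 2),
    L = c(10, 11, 12, 13, 20, 21, 22, 23),
    A = c(5, 6, 7, 8, 15, 16, 17, 18))
  m$R <- m$A / m$L^2
  m$theta_ventral <- rep(c(-0.5, -0.4, -0.3, -0.2), 2)
  out <- normalize_and_reparameterize(m)
  for (b in 1:2) {
    sub <- out[out$bin == b, ]
    ref <- which(sub$L_norm == 1)
    expect_length(ref, 1L)
    expect_equal(sub$A_norm[ref], 1)
  }
  expect_equal(out$s_pos[out$theta_ventral == -0.5][1L],
               -elliptic_arc(0.5, 0.92))
})

test_that("the pipeline is equivariant under rigid motions", {
  sim <- generate_tracks(generator_params(n_nuclei = 150L, n_rows = 3L,
                                          n_timepoints = 6L,
                                          noise_sigma = 0.2, seed = 7L))
  res1 <- suppressWarnings(run_kinematics(sim$tracks, n_bins = 3L))
  tr2 <- rotate_tracks(sim$tracks, rot3(0.6), shift = c(30, -12, 5))
  res2 <- suppressWarnings(run_kinematics(tr2, n_bins = 3L))
  expect_equal(res1$bins, res2$bins)
  expect_equal(res1$metrics$L, res2$metrics$L, tolerance = 1e-6)
  expect_equal(res1$metrics$A, res2$metrics$A, tolerance = 1e-6)
  expect_equal(res1$metrics$R, res2$metrics$R, tolerance = 1e-6)
})

test_that("the stage changepoint detector finds a clean kink", {
  tt <- 1:40
  vv <- c(rep(1, 25), 1 - 0.04 * (1:15)) + stats::rnorm(40, 0, 1e-3)
  set.seed(1)
  cp <- detect_stage_change(tt, vv)
  expect_true(abs(cp$changepoint - 25) <= 2)
})
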