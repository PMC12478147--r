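# Surface geometry, ring evaluation and constrained minimization.

test_that("geometry evaluator matches sphere and ellipsoid closed forms", {
  sp <- surface_spec("sphere", radius = 1)
  g <- surface_geometry(sp)
  pts <- cbind(c(0.3, 1.2, 2.0), c(0.1, 2.5, -1.0))
  pc <- g$principal(pts[, 1L], pts[, 2L])
  expect_lt(max(abs(pc - 1)), 1e-6)
  el <- surface_geometry(surface_spec("ellipsoid", c(2.5, 1, 1)))
  pole <- el$principal(1e-7, 0)
  expect_equal(as.numeric(pole), c(2.5, 2.5), tolerance = 1e-5)
  # unit ellipsoid agrees with the sphere everywhere
  s1 <- surface_geometry(surface_spec("ellipsoid", c(1, 1, 1)))
  u <- seq(0.2, 3, length.out = 7); v <- seq(-3, 3, length.out = 7)
  expect_lt(max(abs(s1$embed(u, v) - g$embed(u, v))), 1e-12)
  expect_lt(max(abs(s1$principal(u, v) - g$principal(u, v))), 1e-10)
  expect_error(surface_spec("ellipsoid", c(1, 0, 1)),
               class = "morphoring_degenerate_surface")
})

test_that("ring evaluation reproduces spherical-cap closed forms", {
  sp <- surface_spec("sphere", radius = 1)
  r <- evaluate_ring(ring_coeffs_circle(pi / 6), sp)
  expect_equal(r$length, pi, tolerance = 1e-10)
  expect_equal(r$area_enclosed, 2 * pi * (1 - cos(pi / 6)),
               tolerance = 1e-6)
  expect_equal(mean(abs(r$samples$kappa_g)), sqrt(3), tolerance = 1e-8)
  eq <- evaluate_ring(ring_coeffs_circle(pi / 2), sp)
  expect_lt(eq$energy, 1e-12)
  eqf <- evaluate_ring(ring_coeffs_circle(pi / 2), sp,
                       energy_kind = "full-space-curve")
  expect_equal(eqf$energy, pi, tolerance = 1e-10)
  # every sample satisfies the implicit surface equation
  g <- surface_geometry(sp)
  expect_lt(max(abs(g$implicit(as.matrix(r$samples[, c("x", "y", "z")])))),
            1e-8)
})

test_that("enclosed area matches a triangulated mesh oracle on the ellipsoid", {
  ax <- c(2.5, 1, 1)
  sp <- surface_spec("ellipsoid", ax)
  u0 <- 0.8
  r <- evaluate_ring(ring_coeffs_circle(u0), sp)
  expect_equal(r$area_enclosed, cap_area_mesh(ax, u0), tolerance = 1e-4)
})

test_that("constrained minimization recovers the geodesic circle", {
  sp <- surface_spec("sphere", radius = 1)
  alpha <- pi / 6
  ring <- minimize_surface_ring(sp, L_target = pi,
                                A_target = 2 * pi * (1 - cos(alpha)))
  E_circ <- 0.5 * (cos(alpha) / sin(alpha))^2 * 2 * pi * sin(alpha)
  expect_equal(ring$energy, E_circ, tolerance = 1e-5)
  expect_lt(ring$constraint_residuals["length"], 1e-5)
  expect_lt(ring$constraint_residuals["area"], 1e-5)
  os <- orientation_statistic(ring)
  expect_lt(attr(os, "magnitude"), 1e-4)
})

test_that("self-intersecting rings are rejected", {
  co <- ring_coeffs_circle(0.5)
  co[3L] <- 0.65          # large second-harmonic wobble pinches the curve
  sp <- surface_spec("sphere", radius = 1)
  expect_error(evaluate_ring(co, sp),
               class = "morphoring_self_intersecting")
})

test_that("symmetry images of ring coefficients preserve the energy exactly", {
  sp <- surface_spec("sphere", radius = 1)
  co <- ring_coeffs_circle(pi / 5)
  set.seed(3)
  co[2:5] <- 0.03 * stats::rnorm(4L)
  co[15L + 2:4] <- 0.02 * stats::rnorm(3L)
  base <- evaluate_ring(co, sp, check_self_intersection = FALSE)
  for (im in c("mirror", "swap", "both")) {
    img <- evaluate_ring(ring_coeffs_transform(co, im), sp,
                         check_self_intersection = FALSE)
    expect_equal(img$energy, base$energy, tolerance = 1e-10)
    expect_equal(img$length, base$length, tolerance = 1e-10)
    expect_equal(img$area_enclosed, base$area_enclosed, tolerance = 1e-8)
  }
})

test_that("the orientation statistic tracks the triangular phase", {
  # a triangular ring around the pole of a sphere: flipping the sign of
  # the third colatitude harmonic turns the triangle into its opposite
  # orientation and must flip the signed statistic
  sp <- surface_spec("sphere", radius = 1)
  co <- ring_coeffs_circle(0.5)
  co[1L + 3L] <- 0.06                  # third harmonic in the colatitude
  r1 <- evaluate_ring(co, sp, check_self_intersection = FALSE)
  s1 <- orientation_statistic(r1)
  expect_gt(attr(s1, "magnitude"), 0.01)
  co2 <- co
  co2[1L + 3L] <- -co[1L + 3L]
  r2 <- evaluate_ring(co2, sp, check_self_intersection = FALSE)
  s2 <- orientation_statistic(r2)
  expect_equal(as.numeric(s2), -as.numeric(s1), tolerance = 1e-4)
  expect_equal(attr(s2, "magnitude"), attr(s1, "magnitude"),
               tolerance = 1e-4)
})
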