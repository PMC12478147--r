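# Constrained planar elastica: solver correctness and invariants.

test_that("the undeformed circle is recovered exactly at (d0, A0)", {
  sol <- solve_half_ring_bvp(2 / pi, 1 / pi, seed = "circle")
  expect_s3_class(sol, "elastica_ring")
  expect_equal(sol$branch, "circle")
  expect_lt(max(abs(abs(sol$profile$kappa) - pi)), 1e-10)
  expect_equal(sol$energy, pi^2, tolerance = 1e-10)
})

test_that("converged solutions satisfy the boundary and area constraints", {
  cases <- list(c(2 / pi, 0.9 / pi), c(0.58, 0.26), c(0.7, 0.28))
  for (cs in cases) {
    sol <- solve_half_ring_bvp(cs[1L], cs[2L], seed = "asymmetric")
    pr <- sol$profile
    n <- nrow(pr)
    expect_lt(abs(pr$theta[1L] - pi / 2), 1e-8)
    expect_lt(abs(pr$theta[n] + pi / 2), 1e-8)
    expect_lt(max(abs(c(pr$x[1L], pr$y[1L], pr$y[n]))), 1e-8)
    expect_lt(abs(pr$x[n] - cs[1L]), 1e-8)
    expect_lt(abs(pr$area_cum[n] - cs[2L]), 1e-8)
    # inextensibility: reconstructed half-curve arclength equals 1
    expect_lt(abs(spline_arclength(pr$s, pr$x, pr$y) - 1), 1e-8)
    # total turning of the half-ring is -pi
    expect_lt(abs((pr$theta[n] - pr$theta[1L]) + pi), 1e-8)
    # stationarity: the curvature ODE residual is small on the profile
    # (limited by the spline second derivative of the sampled curvature)
    kpp <- stats::splinefun(pr$s, pr$kappa)(pr$s, deriv = 2L)
    resid <- kpp + pr$kappa^3 / 2 - sol$lambda0 * pr$kappa + sol$p
    expect_lt(stats::median(abs(resid)) / (1 + abs(sol$p)), 1e-3)
  }
})

test_that("bending energy is bounded below by the circle's", {
  for (A_rel in c(0.95, 0.85, 0.7)) {
    sol <- solve_half_ring_bvp(2 / pi, A_rel / pi, seed = "asymmetric")
    expect_gt(sol$energy, pi^2)
  }
})

test_that("ring_energy matches the closed form for constant curvature", {
  sol <- solve_half_ring_bvp(2 / pi, 1 / pi, seed = "circle")
  expect_equal(ring_energy(sol), pi^2, tolerance = 1e-12)
})

test_that("infeasible constraints are rejected with informative errors", {
  expect_error(solve_half_ring_bvp(1.2, 0.1), class = "morphoring_infeasible")
  expect_error(solve_half_ring_bvp(0.5, 1), class = "morphoring_infeasible")
  expect_error(solve_half_ring_bvp(0.5, -0.1),
               class = "morphoring_infeasible")
})

test_that("AP reflection maps solutions to solutions of equal energy", {
  sol <- solve_half_ring_bvp(2 / pi, 0.85 / pi, seed = "asymmetric")
  ref <- morphoring:::reflect_solution(sol)
  expect_equal(ref$energy, sol$energy)
  expect_equal(ref$profile$kappa, rev(sol$profile$kappa), tolerance = 1e-10)
  # reflected curve still satisfies the boundary conditions
  n <- nrow(ref$profile)
  expect_lt(max(abs(c(ref$profile$x[1L], ref$profile$y[1L],
                      ref$profile$y[n], ref$profile$x[n] - sol$d))), 1e-8)
})

test_that("maximum enclosable area follows the two-arc bound", {
  expect_equal(max_area_for_diameter(2 / pi), 1 / pi, tolerance = 1e-12)
  expect_equal(max_area_for_diameter(1), 0)
  # independent discrete maximizer agrees at d = 0.5
  expect_equal(max_area_for_diameter(0.5), polygon_max_area(0.5),
               tolerance = 1e-4)
  expect_error(max_area_for_diameter(1.2), class = "morphoring_infeasible")
})

test_that("keyhole energy matches the discrete polygon minimizer", {
  sol <- solve_half_ring_bvp(2 / pi, 0.85 / pi, seed = "asymmetric")
  pol <- ring_polygon_minimize(2 / pi, 0.85 / pi, n_seg = 200L)
  expect_lt(max(abs(pol$constraints)), 1e-8)
  expect_lt(abs(pol$energy / sol$energy - 1), 0.005)
})

test_that("the unreduced polygon admits a lower oblique mode excluded by the boundary conditions", {
  set.seed(1)
  pol <- ring_polygon_minimize(2 / pi, 0.85 / pi, n_seg = 100L,
                               symmetric = FALSE, perturb = 2)
  sym <- ring_polygon_minimize(2 / pi, 0.85 / pi, n_seg = 100L)
  expect_lt(pol$energy, sym$energy)
  # the oblique minimizer is point-symmetric about (d/2, 0)
  v <- pol$vertices
  n <- 100L
  up <- v[2:(n / 2), ]; lo <- v[(n / 2 + 2L):n, ]
  expect_lt(max(abs(up[, 1L] + lo[, 1L] - 2 / pi),
                abs(up[, 2L] + lo[, 2L])), 1e-4)
})
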