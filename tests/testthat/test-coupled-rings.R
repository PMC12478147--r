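# Coupled-ring offset model: closed forms, oracles and monotone trends.

test_that("ellipse perimeter matches circles and a dense polygon", {
  expect_equal(ellipse_perimeter(1, 1), 2 * pi, tolerance = 1e-12)
  expect_equal(ellipse_perimeter(3, 3), 6 * pi, tolerance = 1e-12)
  # dense polygonal arclength oracle
  t <- seq(0, 2 * pi, length.out = 1e6 + 1)
  L_poly <- sum(sqrt(diff(2 * cos(t))^2 + diff(sin(t))^2))
  expect_equal(ellipse_perimeter(2, 1), L_poly, tolerance = 1e-8)
  # monotone in the semimajor axis
  a <- seq(1, 3, by = 0.25)
  expect_true(all(diff(ellipse_perimeter(a, 1)) > 0))
})

test_that("parallel-curve closed forms match the polygon offset oracle", {
  # circle
  out <- offset_curve_metrics(2 * pi, pi, 0.1, "outward")
  expect_equal(unname(out["L"]), 2 * pi * 1.1, tolerance = 1e-12)
  expect_equal(unname(out["A"]), pi * 1.21, tolerance = 1e-12)
  # 2:1 ellipse, outward and inward
  L_mid <- ellipse_perimeter(2, 1); A_mid <- 2 * pi
  for (case in list(c(0.2, 1), c(0.3, -1))) {
    h <- case[1L]; sgn <- case[2L]
    dir <- if (sgn > 0) "outward" else "inward"
    out <- offset_curve_metrics(L_mid, A_mid, h, dir, min_radius = 0.5)
    orc <- ellipse_offset_polygon(2, 1, sgn * h)
    expect_equal(unname(out["L"]), unname(orc["L"]), tolerance = 1e-6)
    expect_equal(unname(out["A"]), unname(orc["A"]), tolerance = 1e-6)
  }
})

test_that("inward offsets beyond the curvature radius are rejected", {
  expect_error(
    offset_curve_metrics(ellipse_perimeter(2, 1), 2 * pi, 0.6, "inward",
                         min_radius = 0.5),
    class = "morphoring_offset_too_large")
})

test_that("offsetting out then in recovers the middle curve exactly", {
  L <- ellipse_perimeter(2, 1); A <- 2 * pi; h <- 0.17
  out <- offset_curve_metrics(L, A, h, "outward")
  back <- offset_curve_metrics(unname(out["L"]), unname(out["A"]), h,
                               "inward")
  expect_equal(unname(back["L"]), L, tolerance = 1e-14)
  expect_equal(unname(back["A"]), A, tolerance = 1e-14)
})

test_that("growing offsets at constant middle length split inner/outer trends", {
  st <- tibble::tibble(f_x = rep(10, 8), f_y = rep(10, 8),
                       d_i = seq(1, 3, length.out = 8),
                       d_o = seq(1, 3, length.out = 8))
  pr <- coupled_ring_predict(st, "constant-length")
  expect_true(all(diff(pr$L_in) < 0))
  expect_true(all(diff(pr$L_out) > 0))
  expect_true(all(diff(pr$A_in) < 0))
  expect_true(all(diff(pr$A_out) > 0))
  # zero offsets collapse all three rings
  st0 <- tibble::tibble(f_x = c(10, 9), f_y = c(10, 11),
                        d_i = 0, d_o = 0)
  pr0 <- coupled_ring_predict(st0, "constant-length")
  expect_equal(pr0$L_in, pr0$L_mid)
  expect_equal(pr0$A_out, pr0$A_mid)
})

test_that("area-preserving elongation still shrinks the inner ring area", {
  f_y <- seq(10, 14, length.out = 6)
  st <- tibble::tibble(f_y = f_y, f_x = 100 / f_y,
                       d_i = 1.5, d_o = 1.5)
  pr <- coupled_ring_predict(st, "constant-area")
  expect_lt(max(abs(pr$A_mid - pr$A_mid[1L])), 1e-9)
  expect_true(all(diff(pr$A_in) < 0))   # perimeter grows, so A_in falls
})
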