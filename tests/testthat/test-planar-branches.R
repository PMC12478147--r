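# Branch enumeration, the four-fold degenerate keyhole family, and the
# phase diagram.

test_that("enumeration at reduced area finds the degenerate keyhole family", {
  br <- suppressWarnings(enumerate_branches(2 / pi, 0.85 / pi,
                                            n_mesh = 151L))
  tb <- tidy(br)
  asym <- tb[grepl("^asymmetric", tb$branch), ]
  sym <- tb[grepl("^symmetric", tb$branch), ]
  expect_gte(nrow(tb), 5L)
  expect_equal(nrow(asym), 4L)
  # exact four-fold degeneracy from the pairing construction
  expect_lt(diff(range(asym$energy)) / mean(asym$energy), 1e-12)
  # strictly below every AP-symmetric branch
  expect_gt(nrow(sym), 0L)
  expect_lt(max(asym$energy), min(sym$energy))
  # the four members are images under the reflections: their half-ring
  # curvature profiles map onto each other under s -> 1 - s
  ks <- lapply(br[grepl("^asymmetric", vapply(br, `[[`, "", "branch"))],
               function(m) m$profile$kappa)
  d12 <- min(sqrt(mean((ks[[1]] - ks[[2]])^2)),
             sqrt(mean((ks[[1]] - rev(ks[[2]]))^2)))
  expect_lt(d12 / sqrt(mean(ks[[1]]^2)), 1e-6)
})

test_that("the circle is the only branch at the reference point", {
  br <- enumerate_branches(2 / pi, 1 / pi)
  expect_equal(length(br), 1L)
  expect_equal(br[[1L]]$branch, "circle")
})

test_that("full-ring curves close and realize the skew pairings", {
  br <- suppressWarnings(enumerate_branches(2 / pi, 0.85 / pi,
                                            n_mesh = 121L))
  for (m in br[1:4]) {
    fr <- full_ring_curve(m)
    expect_equal(nrow(fr), 2L * nrow(m$profile) - 1L)
    expect_lt(sqrt((fr$x[1L] - fr$x[nrow(fr)])^2 +
                     (fr$y[1L] - fr$y[nrow(fr)])^2), 1e-8)
  }
  # among the four members, two are bilaterally symmetric about the AP
  # axis and two are skew
  sym_flags <- vapply(br[1:4], function(m) {
    fr <- full_ring_curve(m)
    n <- nrow(fr)
    up <- fr[fr$s <= 1, ]
    lo <- fr[fr$s >= 1, ]
    yl <- stats::approx(2 - lo$s, lo$y, xout = up$s)$y
    max(abs(up$y + yl), na.rm = TRUE) < 1e-6
  }, logical(1))
  expect_equal(sum(sym_flags), 2L)
})

test_that("phase diagram flags inaccessible cells and classifies the keyhole region", {
  pd <- scan_phase_diagram(seq(0.9, 1.1, length.out = 3) * 2 / pi,
                           seq(0.75, 0.95, length.out = 3) / pi,
                           n_mesh = 81L)
  expect_s3_class(pd, "ring_phase_diagram")
  expect_equal(nrow(pd), 9L)
  # accessibility is monotone in A within each column
  for (dj in unique(pd$d)) {
    col <- pd[pd$d == dj, ]
    col <- col[order(-col$A), ]
    expect_true(all(diff(col$accessible) >= 0))
  }
  # the cell at (d0, 0.85 A0) is asymmetric-lowest
  i <- which.min((pd$d_rel - 1)^2 + (pd$A_rel - 0.85)^2)
  expect_equal(pd$lowest_class[i], "asymmetric")
  # energies: lowest class has the smaller energy
  acc <- pd[pd$lowest_class %in% c("asymmetric", "symmetric"), ]
  expect_true(all(
    (acc$lowest_class == "asymmetric") ==
      (acc$E_asymmetric <= acc$E_symmetric)))
})
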