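# Cubic smoothing spline with the csaps parameterization:
# minimize  p * sum_i (y_i - f(x_i))^2 + (1 - p) * int f''(x)^2 dx
# over natural cubic splines f with knots at the sites x.  p = 1 gives the
# interpolating natural spline, p -> 0 the least-squares line.
#
# Standard Reinsch linear algebra: with gamma the second derivatives at the
# interior knots, Q the (n x (n-2)) second-difference matrix and T the
# (n-2) tridiagonal matrix with T[i,i] = (h_i + h_{i+1})/3 and off-diagonal
# h/6 (so that int f''^2 = gamma' T gamma and the natural-spline continuity
# relation reads T gamma = Q' a),
#   (p * T + (1-p) * Q'Q) gamma = p * Q' y,
#   a = y - (1-p)/p * Q gamma
# gives the smoothed values a; the natural cubic interpolant of (x, a) is
# the minimizer.

csaps_fit <- function(x, y, p) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n, p > 0, p <= 1)
  h <- diff(x)
  if (any(h <= 0)) rlang::abort("sites must be strictly increasing")
  if (p == 1) {
    return(stats::splinefun(x, y, method = "natural"))
  }
  i <- seq_len(n - 2L)
  # Q: n x (n-2), columns are second-difference stencils
  q1 <- 1 / h[i]
  q3 <- 1 / h[i + 1L]
  q2 <- -(q1 + q3)
  # T: (n-2) tridiagonal, T[i,i] = (h_i + h_{i+1})/3, off-diag h_{i+1}/6
  Td <- (h[i] + h[i + 1L]) / 3
  To <- h[i + 1L][-(n - 2L)] / 6
  # assemble sparse and solve
  Q <- Matrix::sparseMatrix(
    i = c(i, i + 1L, i + 2L), j = rep(i, 3L), x = c(q1, q2, q3),
    dims = c(n, n - 2L))
  Tm <- Matrix::bandSparse(n - 2L, k = c(-1L, 0L, 1L),
                           diagonals = list(To, Td, To), symmetric = FALSE)
  lhs <- (1 - p) * Matrix::crossprod(Q) + p * Tm
  gamma <- as.numeric(Matrix::solve(lhs, p * Matrix::crossprod(Q, y)))
  a <- y - (1 - p) / p * as.numeric(Q %*% gamma)
  stats::splinefun(x, a, method = "natural")
}

# smoothed values at the sites only
csaps_values <- function(x, y, p) csaps_fit(x, y, p)(x)
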