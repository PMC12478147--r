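# Test-local numerical oracles, independent of the package's main
# computational paths.

# arclength of the curve (x(s), y(s)) from spline fits of the sampled
# profile (checks inextensibility independently of the ODE states)
spline_arclength <- function(s, x, y) {
  fx <- stats::splinefun(s, x)
  fy <- stats::splinefun(s, y)
  sq <- seq(min(s), max(s), length.out = 4001L)
  integrand <- sqrt(fx(sq, deriv = 1L)^2 + fy(sq, deriv = 1L)^2)
  h <- sq[2L] - sq[1L]
  w <- rep(c(2, 4), length.out = 4001L); w[1L] <- 1; w[4001L] <- 1
  sum(w * integrand) * h / 3
}

# brute-force maximizer of the enclosed area of a half-curve of length 1
# through (0,0) and (d,0): M equal segments, headings free, area between
# curve and chord maximized by penalized ascent.  Doubling gives the full
# ring area bound.
polygon_max_area <- function(d, M = 200L) {
  h <- 1 / M
  obj <- function(phi, mu) {
    x <- h * cumsum(cos(phi)); y <- h * cumsum(sin(phi))
    xs <- c(0, x); ys <- c(0, y)
    i <- seq_len(M)
    area <- 0.5 * sum(xs[i] * ys[i + 1L] - xs[i + 1L] * ys[i])
    -area + mu * ((x[M] - d)^2 + y[M]^2)
  }
  phi <- seq(pi / 2, -pi / 2, length.out = M)
  mu <- 100
  for (k in 1:6) {
    phi <- stats::optim(phi, obj, mu = mu, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-13))$par
    mu <- mu * 10
  }
  x <- h * cumsum(cos(phi)); y <- h * cumsum(sin(phi))
  xs <- c(0, x); ys <- c(0, y)
  i <- seq_len(M)
  2 * abs(0.5 * sum(xs[i] * ys[i + 1L] - xs[i + 1L] * ys[i]))
}

# polygon normal-offset oracle for an ellipse (a, b): length and area of
# the parallel curve at signed distance h (positive outward)
ellipse_offset_polygon <- function(a, b, h, n = 1e4L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  # outward unit normal of the ellipse
  nx <- b * cos(t); ny <- a * sin(t)
  nn <- sqrt(nx^2 + ny^2)
  px <- x + h * nx / nn; py <- y + h * ny / nn
  i2 <- c(2:n, 1L)
  L <- sum(sqrt((px[i2] - px)^2 + (py[i2] - py)^2))
  A <- 0.5 * abs(sum(px * py[i2] - px[i2] * py))
  c(L = L, A = A)
}

# triangulated surface-area oracle for the pole-side cap bounded by a
# latitude circle u = u0 on an ellipsoid
cap_area_mesh <- function(ax, u0, nu = 400L, nv = 400L) {
  uu <- seq(1e-6, u0, length.out = nu)
  vv <- seq(0, 2 * pi, length.out = nv + 1L)
  emb <- function(u, v) {
    cbind(ax[1L] * cos(u), ax[2L] * sin(u) * cos(v),
          ax[3L] * sin(u) * sin(v))
  }
  total <- 0
  for (i in seq_len(nu - 1L)) {
    P00 <- emb(uu[i], vv[-(nv + 1L)])
    P10 <- emb(uu[i + 1L], vv[-(nv + 1L)])
    P01 <- emb(uu[i], vv[-1L])
    P11 <- emb(uu[i + 1L], vv[-1L])
    cr <- function(u, v) {
      cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
            u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
            u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
    }
    a1 <- 0.5 * sqrt(rowSums(cr(P10 - P00, P01 - P00)^2))
    a2 <- 0.5 * sqrt(rowSums(cr(P10 - P11, P01 - P11)^2))
    total <- total + sum(a1) + sum(a2)
  }
  total
}

# rigid rotation helper
rotate_tracks <- function(tracks, Rm, shift = c(0, 0, 0)) {
  P <- as.matrix(tracks[, c("x_um", "y_um", "z_um")]) %*% t(Rm)
  tracks$x_um <- P[, 1L] + shift[1L]
  tracks$y_um <- P[, 2L] + shift[2L]
  tracks$z_um <- P[, 3L] + shift[3L]
  tracks
}

rot3 <- function(ax_angle) {
  # rotation about a fixed skew axis by the given angle
  th <- ax_angle
  u <- c(1, 2, 3) / sqrt(14)
  K <- rbind(c(0, -u[3L], u[2L]), c(u[3L], 0, -u[1L]),
             c(-u[2L], u[1L], 0))
  diag(3L) + sin(th) * K + (1 - cos(th)) * K %*% K
}
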