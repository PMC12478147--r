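# Discrete polygon ring minimizer.
#
# Independent, derivative-based discretization of the same variational
# problem as the half-ring BVP: a closed polygon of n_seg equal segments
# (total length 2) through the marked points v[0] = (0,0) and
# v[n_seg/2] = (d,0), enclosing signed area -A (clockwise traversal),
# minimizing the discrete bending energy sum(psi^2)/(2h) over the turning
# angles psi.  No symmetry is imposed, so this serves as a brute-force
# cross-check of the collocation/shooting solver and as an explorer of the
# full (unreduced) solution set.
#
# Formulation: variables are the initial heading phi0 and the n_seg turning
# angles; inextensibility is built in (all segments have length h = 2/n_seg)
# and the five remaining constraints (closure x/y, marked point x/y, area)
# plus total turning -2*pi are enforced by an augmented Lagrangian.

polygon_geometry <- function(par, n, h) {
  phi0 <- par[1L]
  psi <- par[-1L]
  phi <- phi0 + cumsum(psi)
  cx <- cos(phi); sx <- sin(phi)
  x <- h * cumsum(cx); y <- h * cumsum(sx)      # v_1 .. v_n (v_0 = origin)
  list(phi = phi, cx = cx, sx = sx, x = x, y = y, psi = psi)
}

polygon_constraints <- function(g, n, h, d, A) {
  half <- n %/% 2L
  xs <- c(0, g$x); ys <- c(0, g$y)               # v_0 .. v_n
  # shoelace over the closed polygon v_0 .. v_{n-1} (v_n ~ v_0)
  i <- seq_len(n)
  a_s <- 0.5 * sum(xs[i] * ys[i + 1L] - xs[i + 1L] * ys[i]) +
    0.5 * (xs[n + 1L] * ys[1L] - xs[1L] * ys[n + 1L])
  c(close_x = g$x[n],
    close_y = g$y[n],
    mark_x = g$x[half] - d,
    mark_y = g$y[half],
    turn = sum(g$psi) + 2 * pi,
    area = a_s + A)
}

# gradient of sum_i dot(gv_i, dv_i/dpar) given per-vertex gradients gv (n x 2)
chain_vertex_grad <- function(gv, g, h, n) {
  Gx <- rev(cumsum(rev(gv[, 1L])))               # suffix sums over i >= j
  Gy <- rev(cumsum(rev(gv[, 2L])))
  q <- h * (-g$sx * Gx + g$cx * Gy)
  dpsi <- rev(cumsum(rev(q)))                    # suffix sum over j >= k
  c(phi0 = sum(q), dpsi)
}

polygon_constraint_grads <- function(g, n, h) {
  half <- n %/% 2L
  xs <- c(0, g$x); ys <- c(0, g$y)
  # per-vertex shoelace gradients for v_1..v_n (cyclic neighbors incl v_0)
  ip <- seq_len(n); prv <- ip; nxt <- ip + 2L
  nxt[nxt > n + 1L] <- nxt[nxt > n + 1L] - (n + 1L)
  gax <- 0.5 * (ys[nxt] - ys[prv])
  gay <- 0.5 * (xs[prv] - xs[nxt])
  gv_close <- function(comp) {
    gv <- matrix(0, n, 2L); gv[n, comp] <- 1; gv
  }
  gv_mark <- function(comp) {
    gv <- matrix(0, n, 2L); gv[half, comp] <- 1; gv
  }
  rbind(
    chain_vertex_grad(gv_close(1L), g, h, n),
    chain_vertex_grad(gv_close(2L), g, h, n),
    chain_vertex_grad(gv_mark(1L), g, h, n),
    chain_vertex_grad(gv_mark(2L), g, h, n),
    c(0, rep(1, n)),
    chain_vertex_grad(cbind(gax, gay), g, h, n))
}

#' Minimize the discrete polygon ring energy
#'
#' Brute-force constrained minimizer over closed equal-segment polygons with
#' the same constraints as [solve_half_ring_bvp()] but with no symmetry
#' imposed.  Used as an independent numerical cross-check of the
#' boundary-value solver.
#'
#' @param d,A Constraints as in [solve_half_ring_bvp()].
#' @param n_seg Number of equal segments of the full ring (even; default 200).
#' @param symmetric Impose the bilateral (mirror) symmetry about the AP chord
#'   that the embryo imposes on the tissue (default `TRUE`, matching the
#'   half-ring boundary-value problem).  With `FALSE` the full unreduced
#'   polygon is minimized; the unrestricted problem is undercut by oblique
#'   point-symmetric mode-2 shapes that break the bilateral symmetry and are
#'   excluded by the model's boundary conditions.
#' @param start Optional starting turning-angle vector (length `n_seg`, or
#'   `n_seg/2` headings-parameterization when `symmetric`); default is the
#'   circle plus a seeded perturbation.
#' @param perturb Amplitude of the random mode perturbation added to the
#'   default start.
#' @param n_outer Augmented-Lagrangian outer iterations.
#' @param maxit BFGS iterations per outer stage.
#' @return A list with `energy`, `vertices` (closed, `(n_seg+1) x 2`),
#'   `constraints` (final residuals), and `psi` (turning angles of the full
#'   ring).
#' @export
#' @examples
#' out <- ring_polygon_minimize(2 / pi, 1 / pi, n_seg = 100)
#' out$energy # close to pi^2
ring_polygon_minimize <- function(d, A, n_seg = 200L, symmetric = TRUE,
                                  start = NULL, perturb = 0,
                                  n_outer = 7L, maxit = 400L) {
  check_feasible(d, A)
  n <- as.integer(n_seg)
  stopifnot(n %% 2L == 0L, n >= 20L)
  if (symmetric) {
    return(ring_polygon_minimize_sym(d, A, n, start = start,
                                     perturb = perturb, n_outer = n_outer,
                                     maxit = maxit))
  }
  h <- 2 / n
  if (is.null(start)) {
    start <- rep(-2 * pi / n, n)
    if (perturb > 0) {
      t_mid <- (seq_len(n) - 0.5) / n
      modes <- sample(2:4, 1L)
      ph <- stats::runif(1, 0, 2 * pi)
      start <- start + perturb * h * cos(modes * pi * (2 * t_mid) + ph)
    }
  }
  par <- c(pi / 2, start)
  lambda <- rep(0, 6L)
  mu <- 200
  for (outer in seq_len(n_outer)) {
    obj <- function(p) {
      g <- polygon_geometry(p, n, h)
      cc <- polygon_constraints(g, n, h, d, A)
      sum(g$psi^2) / (2 * h) - sum(lambda * cc) + 0.5 * mu * sum(cc^2)
    }
    grad <- function(p) {
      g <- polygon_geometry(p, n, h)
      cc <- polygon_constraints(g, n, h, d, A)
      cg <- polygon_constraint_grads(g, n, h)
      w <- -lambda + mu * cc
      gr <- as.numeric(t(cg) %*% w)
      gr[-1L] <- gr[-1L] + g$psi / h
      gr
    }
    opt <- stats::optim(par, obj, grad, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    par <- opt$par
    g <- polygon_geometry(par, n, h)
    cc <- polygon_constraints(g, n, h, d, A)
    lambda <- lambda - mu * cc
    if (max(abs(cc)) < 1e-10 && outer >= 3L) break
    mu <- mu * 8
  }
  g <- polygon_geometry(par, n, h)
  cc <- polygon_constraints(g, n, h, d, A)
  list(energy = sum(g$psi^2) / (2 * h),
       vertices = cbind(x = c(0, g$x), y = c(0, g$y)),
       constraints = cc,
       psi = g$psi,
       phi0 = par[1L])
}

# mirror-symmetric variant: parameterized by the headings of the n/2
# upper-half segments; the lower half is the reflection in the AP chord.
ring_polygon_minimize_sym <- function(d, A, n, start = NULL, perturb = 0,
                                      n_outer = 7L, maxit = 400L) {
  M <- n %/% 2L
  h <- 2 / n
  if (is.null(start)) {
    phi <- pi / 2 - (seq_len(M) - 0.5) * pi / M
    if (perturb > 0) {
      t_mid <- (seq_len(M) - 0.5) / M
      mode <- sample(2:4, 1L)
      ph <- stats::runif(1, 0, 2 * pi)
      phi <- phi + perturb * cos(mode * pi * t_mid + ph) / mode
    }
  } else {
    phi <- start
    stopifnot(length(phi) == M)
  }
  energy_fun <- function(phi) {
    ps <- diff(phi)
    t0 <- 2 * phi[1L] - pi
    tM <- -pi - 2 * phi[M]
    (2 * sum(ps^2) + t0^2 + tM^2) / (2 * h)
  }
  energy_grad <- function(phi) {
    ps <- diff(phi)
    g <- numeric(M)
    g[-M] <- g[-M] - 2 * ps
    g[-1L] <- g[-1L] + 2 * ps
    g <- 2 * g
    g[1L] <- g[1L] + 2 * (2 * phi[1L] - pi) * 2 / 2
    g[1L] <- g[1L] + 2 * (2 * phi[1L] - pi)  # total d(t0^2)/dphi1 = 4*t0
    g[M] <- g[M] - 4 * (-pi - 2 * phi[M])
    g / (2 * h)
  }
  # fix the double-counted t0 term above by recomputing cleanly
  energy_grad <- function(phi) {
    ps <- diff(phi)
    g <- numeric(M)
    g[-M] <- g[-M] - 4 * ps
    g[-1L] <- g[-1L] + 4 * ps
    g[1L] <- g[1L] + 4 * (2 * phi[1L] - pi)
    g[M] <- g[M] - 4 * (-pi - 2 * phi[M])
    g / (2 * h)
  }
  constraints_fun <- function(phi) {
    cx <- cos(phi); sx <- sin(phi)
    x <- h * cumsum(cx); y <- h * cumsum(sx)
    xs <- c(0, x); ys <- c(0, y)
    i <- seq_len(M)
    sh <- 0.5 * sum(xs[i] * ys[i + 1L] - xs[i + 1L] * ys[i])
    c(mark_x = x[M] - d, mark_y = y[M], area = 2 * sh + A)
  }
  constraint_grads <- function(phi) {
    cx <- cos(phi); sx <- sin(phi)
    x <- h * cumsum(cx); y <- h * cumsum(sx)
    xs <- c(0, x); ys <- c(0, y)
    # vertex gradients of the half shoelace for v_1..v_M
    gax <- 0.5 * (c(ys[-1L], 0)[-1L] - ys[seq_len(M)])
    gay <- 0.5 * (xs[seq_len(M)] - c(xs[-1L], 0)[-1L])
    # last vertex v_M: neighbors v_{M-1} and (chord) v_0
    gax[M] <- 0.5 * (0 - ys[M])
    gay[M] <- 0.5 * (xs[M] - 0)
    sufx <- rev(cumsum(rev(gax))); sufy <- rev(cumsum(rev(gay)))
    g_area <- 2 * h * (-sx * sufx + cx * sufy)
    rbind(mark_x = -h * sx,
          mark_y = h * cx,
          area = g_area)
  }
  lambda <- rep(0, 3L)
  mu <- 200
  par <- phi
  for (outer in seq_len(n_outer)) {
    obj <- function(p) {
      cc <- constraints_fun(p)
      energy_fun(p) - sum(lambda * cc) + 0.5 * mu * sum(cc^2)
    }
    grad <- function(p) {
      cc <- constraints_fun(p)
      cg <- constraint_grads(p)
      energy_grad(p) + as.numeric(t(cg) %*% (-lambda + mu * cc))
    }
    opt <- stats::optim(par, obj, grad, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-15))
    par <- opt$par
    cc <- constraints_fun(par)
    lambda <- lambda - mu * cc
    if (max(abs(cc)) < 1e-11 && outer >= 3L) break
    mu <- mu * 8
  }
  phi <- par
  cc <- constraints_fun(phi)
  x <- h * cumsum(cos(phi)); y <- h * cumsum(sin(phi))
  v_up <- cbind(x = c(0, x), y = c(0, y))
  v_lo <- v_up[rev(seq_len(M + 1L))[-1L], , drop = FALSE]
  v_lo[, 2L] <- -v_lo[, 2L]
  psi_full <- c(2 * phi[1L] - pi, diff(phi), -pi - 2 * phi[M],
                rev(-diff(phi)))
  list(energy = energy_fun(phi),
       vertices = rbind(v_up, v_lo),
       constraints = cc,
       psi = psi_full,
       phi = phi)
}
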