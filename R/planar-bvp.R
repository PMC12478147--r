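# Constrained planar elastica: half-ring boundary-value problem.
#
# The ring is an inextensible elastic curve of total length 2 (half-perimeter
# nondimensionalized to 1) that minimizes the bending energy E = (1/2) * the
# integral of kappa^2 over the full ring, subject to a prescribed enclosed
# area A and a prescribed anteroposterior (AP) diameter d between the two
# marked points at arclength s = 0 and s = 1.  Bilateral symmetry about the
# AP axis reduces the problem to the upper half-ring, governed by
#
#   kappa'' + kappa^3/2 - lambda0 * kappa + p = 0,
#   theta' = kappa,  x' = cos(theta),  y' = sin(theta),
#   a' = y*cos(theta) - x*sin(theta)              (cumulative area state)
#
# with boundary conditions theta(0) = pi/2, theta(1) = -pi/2,
# x(0) = y(0) = y(1) = 0, x(1) = d, a(0) = 0, a(1) = A.  The multipliers
# lambda0 (tension) and p (pressure) are unknown constants; with the six
# states this gives a square system (8 conditions, 6 states + 2 parameters).
#
# The solver runs damped Newton iterations on an implicit-midpoint
# collocation discretization (sparse Jacobian), optionally followed by a
# single-shooting refinement with a high-accuracy adaptive integrator so the
# returned profile satisfies the constraints to ~1e-11.

# reference circle: half-perimeter 1 => radius 1/pi
d0_circle <- function() 2 / pi
A0_circle <- function() 1 / pi

# ODE right-hand side; state y = (kappa, kappa', theta, x, y, a)
elastica_rhs <- function(y, lambda0, p) {
  k <- y[1L]; k2 <- y[2L]; th <- y[3L]; x <- y[4L]; yy <- y[5L]
  c(k2,
    -0.5 * k^3 + lambda0 * k - p,
    k,
    cos(th),
    sin(th),
    yy * cos(th) - x * sin(th))
}

# Residual of the collocation system (compiled kernel).
# z = c(as.vector(t(Y)), lambda0, p): states row-major by mesh point.
colloc_residual <- function(z, n, h, d, A) {
  colloc_residual_cpp(z, n, h, d, A)
}

# Sparse Jacobian of colloc_residual wrt z (compiled triplet assembly).
colloc_jacobian <- function(z, n, h) {
  tr <- colloc_jacobian_cpp(z, n, h)
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                       dims = c(6L * n + 2L, 6L * n + 2L))
}

# Damped Newton on the collocation system.  Returns list(z, converged, res).
colloc_newton <- function(z, n, h, d, A, tol = 1e-10, max_iter = 40L,
                          stall_limit = 8L) {
  res <- colloc_residual(z, n, h, d, A)
  rn <- max(abs(res))
  stall <- 0L
  for (it in seq_len(max_iter)) {
    if (rn < tol) break
    J <- colloc_jacobian(z, n, h)
    dz <- tryCatch(as.numeric(Matrix::solve(J, -res)),
                   error = function(e) NULL)
    if (is.null(dz) || any(!is.finite(dz))) {
      return(list(z = z, converged = FALSE, res = rn))
    }
    # backtracking line search on the residual norm
    step <- 1; ok <- FALSE
    for (ls in 1:12) {
      z_new <- z + step * dz
      res_new <- colloc_residual(z_new, n, h, d, A)
      rn_new <- max(abs(res_new))
      if (is.finite(rn_new) && rn_new < rn * (1 - 1e-4 * step) + 1e-14) {
        z <- z_new; res <- res_new
        # stagnation guard: persistent weak damped contractions mean a
        # fold or a bad basin; bail out instead of grinding
        stall <- if (rn_new > 0.8 * rn && step < 1) stall + 1L else 0L
        rn <- rn_new; ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok || stall >= stall_limit) {
      return(list(z = z, converged = rn < tol, res = rn))
    }
  }
  list(z = z, converged = rn < tol, res = rn)
}

# Build a collocation vector from a curvature profile (values at mesh points)
# by integrating the kinematic equations with the trapezoidal rule.
colloc_init_from_kappa <- function(kappa, s, lambda0, p) {
  n <- length(s)
  theta <- pi / 2 + cumtrapz_vec(s, kappa)
  x <- cumtrapz_vec(s, cos(theta))
  y <- cumtrapz_vec(s, sin(theta))
  a <- cumtrapz_vec(s, y * cos(theta) - x * sin(theta))
  kp <- fd_deriv(s, kappa)
  Y <- cbind(kappa, kp, theta, x, y, a)
  c(as.vector(t(Y)), lambda0, p)
}

cumtrapz_vec <- function(s, f) {
  c(0, cumsum((f[-1L] + f[-length(f)]) / 2 * diff(s)))
}

fd_deriv <- function(s, f) {
  n <- length(f)
  d <- numeric(n)
  d[1L] <- (f[2L] - f[1L]) / (s[2L] - s[1L])
  d[n] <- (f[n] - f[n - 1L]) / (s[n] - s[n - 1L])
  d[2:(n - 1L)] <- (f[3:n] - f[1:(n - 2L)]) / (s[3:n] - s[1:(n - 2L)])
  d
}

# --- single-shooting refinement -------------------------------------------

shoot_integrate <- function(q, d, A, n_out = 801L, rtol = 1e-12, atol = 1e-12) {
  y0 <- c(k = q[1L], k2 = q[2L], th = pi / 2, x = 0, y = 0, a = 0)
  par <- c(lambda0 = q[3L], p = q[4L])
  f <- function(s, y, parms) {
    list(elastica_rhs(y, parms[["lambda0"]], parms[["p"]]))
  }
  out <- deSolve::ode(y = y0, times = seq(0, 1, length.out = n_out),
                      func = f, parms = par, method = "lsoda",
                      rtol = rtol, atol = atol)
  out
}

shoot_residual <- function(q, d, A) {
  out <- shoot_integrate(q, d, A, n_out = 2L)
  yf <- out[nrow(out), -1L]
  as.numeric(c(yf["th"] + pi / 2, yf["x"] - d, yf["y"], yf["a"] - A))
}

shoot_refine <- function(q, d, A, tol = 1e-10, max_iter = 16L) {
  G <- shoot_residual(q, d, A)
  for (it in seq_len(max_iter)) {
    if (max(abs(G)) < tol) break
    J <- matrix(0, 4L, 4L)
    for (j in 1:4) {
      eps <- 1e-7 * max(1, abs(q[j]))
      qp <- q; qp[j] <- qp[j] + eps
      qm <- q; qm[j] <- qm[j] - eps
      J[, j] <- (shoot_residual(qp, d, A) - shoot_residual(qm, d, A)) / (2 * eps)
    }
    dq <- tryCatch(solve(J, -G), error = function(e) NULL)
    if (is.null(dq) || any(!is.finite(dq))) break
    step <- 1
    for (ls in 1:8) {
      qn <- q + step * dq
      Gn <- shoot_residual(qn, d, A)
      if (all(is.finite(Gn)) && max(abs(Gn)) < max(abs(G))) {
        q <- qn; G <- Gn; break
      }
      step <- step / 2
    }
  }
  list(q = q, res = max(abs(G)), converged = max(abs(G)) < tol)
}

# Simpson quadrature on a uniform grid (odd number of points).
simpson_uniform <- function(h, f) {
  n <- length(f)
  stopifnot(n %% 2L == 1L)
  w <- rep(c(2, 4), length.out = n)
  w[1L] <- 1; w[n] <- 1
  sum(w * f) * h / 3
}
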