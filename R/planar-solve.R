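# User-facing constrained planar elastica solver.

#' Reference circle constants
#'
#' In the half-perimeter-1 nondimensionalization the undeformed circular ring
#' has AP diameter `d0 = 2/pi` and enclosed area `A0 = 1/pi`.
#'
#' @return A named numeric vector with elements `d0` and `A0`.
#' @export
#' @examples
#' ring_reference()
ring_reference <- function() c(d0 = 2 / pi, A0 = 1 / pi)

#' Describe a branch seed for the half-ring solver
#'
#' Solution branches are reached by perturbing the circular profile with a
#' small-amplitude Fourier mode of the curvature and continuing the solution
#' in the constraints.  Odd cosine modes and even sine modes break the
#' anteroposterior (AP) mirror symmetry `s -> 1 - s` of the half-ring
#' curvature profile; the complementary phases preserve it.
#'
#' @param mode Integer lobe number of the perturbation (2--4 are the modes
#'   relevant near the first bifurcations).
#' @param sign +1 or -1, the sign of the perturbation amplitude.
#' @param phase `"cos"` or `"sin"`: phase of the Fourier perturbation
#'   `sign * amplitude * cos(mode*pi*s)` (resp. `sin`).
#' @param amplitude Dimensionless perturbation amplitude of the curvature
#'   (default 0.1, small against the circle curvature `pi`).
#' @return An object of class `ring_seed`.
#' @export
#' @examples
#' ring_seed(3, phase = "cos")
ring_seed <- function(mode = 3L, sign = 1, phase = c("cos", "sin"),
                      amplitude = 0.1) {
  phase <- match.arg(phase)
  stopifnot(mode >= 1L, sign %in% c(-1, 1), amplitude > 0)
  structure(list(mode = as.integer(mode), sign = sign, phase = phase,
                 amplitude = amplitude),
            class = "ring_seed")
}

seed_from_spec <- function(seed) {
  if (inherits(seed, "ring_seed")) return(seed)
  if (is.character(seed)) {
    return(switch(seed,
      circle     = NULL,
      asymmetric = ring_seed(3L, phase = "cos"),
      symmetric  = ring_seed(2L, phase = "cos"),
      rlang::abort(paste0("unknown seed shortcut '", seed, "'"),
                   class = "morphoring_bad_seed")))
  }
  if (is.null(seed)) return(NULL)
  rlang::abort("seed must be NULL, a shortcut string or a ring_seed()",
               class = "morphoring_bad_seed")
}

seed_kappa <- function(seed, s) {
  base <- rep(-pi, length(s))
  if (is.null(seed)) return(base)
  f <- if (seed$phase == "cos") cos else sin
  base + seed$sign * seed$amplitude * f(seed$mode * pi * s)
}

check_feasible <- function(d, A) {
  if (!is.finite(d) || d <= 0 || d > 1) {
    rlang::abort(sprintf(
      "infeasible diameter d = %.6g: need 0 < d <= 1 (half-perimeter is 1)", d),
      class = "morphoring_infeasible")
  }
  amax <- max_area_for_diameter(d)
  if (!is.finite(A) || A <= 0 || A > amax + 1e-12) {
    rlang::abort(sprintf(
      "infeasible area A = %.6g: need 0 < A <= A_max(d) = %.6g", A, amax),
      class = "morphoring_infeasible")
  }
  invisible(amax)
}

#' Largest area enclosable at a given AP diameter
#'
#' The accessibility boundary of the `(d, A)` phase plane: the maximum area a
#' closed inextensible curve of total length 2 can enclose while passing
#' through two marked points at straight-line distance `d`.  Each half of the
#' optimal curve is a circular arc of length 1 through both points (bulging to
#' opposite sides), so `A_max` follows from the chord equation
#' `sin(phi)/phi = d` and the circular-segment area.
#'
#' @param d AP diameter, `0 < d <= 1`.
#' @return The maximum enclosed area `A_max(d)`.
#' @export
#' @examples
#' max_area_for_diameter(2 / pi) # the isoperimetric optimum 1/pi
max_area_for_diameter <- function(d) {
  vapply(d, function(di) {
    if (!is.finite(di) || di <= 0 || di > 1) {
      rlang::abort(sprintf("d = %.6g outside (0, 1]", di),
                   class = "morphoring_infeasible")
    }
    if (di == 1) return(0)
    # solve sin(phi)/phi = d on (0, pi)
    phi <- stats::uniroot(function(p) sin(p) / p - di,
                          lower = 1e-12, upper = pi - 1e-12,
                          tol = 1e-15)$root
    r <- 1 / (2 * phi)
    2 * r^2 * (phi - sin(phi) * cos(phi))
  }, numeric(1))
}

#' Solve the constrained half-ring elastica boundary-value problem
#'
#' Finds a stationary shape of the bending energy for the inextensible ring
#' with enclosed area `A` and AP diameter `d`, on the branch selected by
#' `seed`.  The solution is continued from the undeformed circle at
#' `(d, A) = (2/pi, 1/pi)` by stepping first in `A` and then in `d`, and is
#' polished by single shooting with an adaptive high-accuracy integrator.
#'
#' @param d AP diameter constraint (dimensionless, `0 < d <= 1`).
#' @param A Enclosed-area constraint (`0 < A <= max_area_for_diameter(d)`).
#' @param seed Branch seed: `"circle"`, `"asymmetric"`, `"symmetric"`, or a
#'   [ring_seed()] descriptor.
#' @param n_mesh Number of collocation mesh points (>= 200 recommended).
#' @param tol Newton tolerance on the collocation residual.
#' @param refine Polish the collocation solution by single shooting
#'   (default `TRUE`); the refined profile satisfies the boundary conditions
#'   and area constraint to about 1e-11.
#' @param n_out Number of arclength samples in the returned profile (odd).
#' @return An object of class `elastica_ring`; see [tidy.elastica_ring()] for
#'   the profile table and [glance.elastica_ring()] for scalar summaries.
#' @export
#' @examples
#' sol <- solve_half_ring_bvp(2 / pi, 1 / pi, seed = "circle")
#' glance(sol)
solve_half_ring_bvp <- function(d, A, seed = "circle", n_mesh = 201L,
                                tol = 1e-10, refine = TRUE, n_out = 801L) {
  check_feasible(d, A)
  seed <- seed_from_spec(seed)
  d0 <- d0_circle(); A0 <- A0_circle()

  if (is.null(seed) && abs(d - d0) < 1e-12 && abs(A - A0) < 1e-12) {
    return(circle_solution(n_out))
  }

  s <- seq(0, 1, length.out = n_mesh)
  h <- s[2L] - s[1L]
  z <- colloc_init_from_kappa(seed_kappa(seed, s), s, pi^2 / 2, 0)

  # continuation path: (d0, A0) -> (d0, A) -> (d, A)
  path_ok <- continuation_run(z, n_mesh, h, d0, A0, d, A, tol)
  if (!path_ok$converged) {
    rlang::abort(sprintf(
      "half-ring collocation failed to converge (residual %.3g at d=%.4g, A=%.4g)",
      path_ok$res, path_ok$d, path_ok$A),
      class = "morphoring_no_convergence")
  }
  z <- path_ok$z
  build_solution(z, n_mesh, d, A, refine = refine, n_out = n_out,
                 seed = seed, tol = tol)
}

# steps A from A0 to A at d0, then d from d0 to d, warm-starting Newton.
continuation_run <- function(z, n, h, d0, A0, d_t, A_t, tol,
                             max_solves = 140L) {
  cur <- list(z = z, d = d0, A = A0)
  legs <- list(c(target = A_t, which = 2), c(target = d_t, which = 1))
  n_solves <- 0L
  for (leg in legs) {
    which_par <- leg[["which"]]
    target <- leg[["target"]]
    val <- if (which_par == 1) cur$d else cur$A
    if (abs(val - target) < 1e-14) next
    step <- (target - val) / 8
    step <- sign(step) * min(abs(step), 0.05)
    first_step <- TRUE
    while (abs(val - target) > 1e-14) {
      stp <- sign(target - val) * min(abs(step), abs(target - val))
      trial_val <- val + stp
      d_try <- if (which_par == 1) trial_val else cur$d
      A_try <- if (which_par == 2) trial_val else cur$A
      # the first step off the (singular) circle needs patient damping;
      # later steps use the stagnation guard to fail fast at branch folds
      nw <- colloc_newton(cur$z, n, h, d_try, A_try, tol = tol,
                          stall_limit = if (first_step) 100L else 8L)
      n_solves <- n_solves + 1L
      if (nw$converged) {
        first_step <- FALSE
        cur <- list(z = nw$z, d = d_try, A = A_try)
        val <- trial_val
        step <- step * 1.6
      } else {
        step <- step / 2
        if (abs(step) < 1e-6 || n_solves >= max_solves) {
          return(list(converged = FALSE, res = nw$res, d = d_try,
                      A = A_try))
        }
      }
      if (n_solves >= max_solves) {
        return(list(converged = FALSE, res = nw$res, d = cur$d, A = cur$A))
      }
    }
  }
  list(converged = TRUE, z = cur$z, d = cur$d, A = cur$A, res = 0)
}

circle_solution <- function(n_out = 801L) {
  s <- seq(0, 1, length.out = n_out)
  profile <- tibble::tibble(
    s = s,
    kappa = rep(-pi, n_out),
    theta = pi / 2 - pi * s,
    x = (1 - cos(pi * s)) / pi,
    y = sin(pi * s) / pi,
    area_cum = (s * pi - sin(pi * s) * cos(pi * s)) / pi^2 +
      sin(pi * s)^2 * 0  # area integrand integral, see below
  )
  # cumulative area for the circle: integral of (1 - cos(pi s))/pi
  profile$area_cum <- (s - sin(pi * s) / pi) / pi
  new_elastica_ring(profile, d = 2 / pi, A = 1 / pi,
                    lambda0 = pi^2 / 2, p = 0, energy = pi^2,
                    branch = "circle",
                    residuals = c(bc = 0, area = 0, ode = 0),
                    refined = TRUE)
}

# assemble an elastica_ring object from a converged collocation vector
build_solution <- function(z, n, d, A, refine = TRUE, n_out = 801L,
                           seed = NULL, tol = 1e-10) {
  Y <- matrix(z[seq_len(6L * n)], nrow = n, ncol = 6L, byrow = TRUE)
  lambda0 <- z[6L * n + 1L]; p <- z[6L * n + 2L]
  q <- c(Y[1L, 1L], Y[1L, 2L], lambda0, p)
  used_shoot <- FALSE
  if (refine) {
    sr <- shoot_refine(q, d, A)
    if (sr$converged) {
      out <- shoot_integrate(sr$q, d, A, n_out = n_out)
      # accept only if the refined profile stayed on the same branch
      k_ref <- stats::approx(out[, "time"], out[, "k"],
                             xout = seq(0, 1, length.out = n))$y
      if (sqrt(mean((k_ref - Y[, 1L])^2)) / (1 + pi) < 0.05) {
        q <- sr$q
        used_shoot <- TRUE
      }
    }
  }
  if (used_shoot) {
    prof <- tibble::tibble(
      s = out[, "time"], kappa = out[, "k"], theta = out[, "th"],
      x = out[, "x"], y = out[, "y"], area_cum = out[, "a"])
    res_bc <- max(abs(c(prof$theta[n_out] + pi / 2, prof$x[n_out] - d,
                        prof$y[n_out])))
    res_area <- abs(prof$area_cum[n_out] - A)
  } else {
    s_out <- seq(0, 1, length.out = n_out)
    prof <- tibble::tibble(
      s = s_out,
      kappa = stats::spline(seq(0, 1, length.out = n), Y[, 1L], xout = s_out)$y,
      theta = stats::spline(seq(0, 1, length.out = n), Y[, 3L], xout = s_out)$y,
      x = stats::spline(seq(0, 1, length.out = n), Y[, 4L], xout = s_out)$y,
      y = stats::spline(seq(0, 1, length.out = n), Y[, 5L], xout = s_out)$y,
      area_cum = stats::spline(seq(0, 1, length.out = n), Y[, 6L],
                               xout = s_out)$y)
    res_bc <- max(abs(c(Y[n, 3L] + pi / 2, Y[n, 4L] - d, Y[n, 5L])))
    res_area <- abs(Y[n, 6L] - A)
  }
  h_out <- prof$s[2L] - prof$s[1L]
  energy <- simpson_uniform(h_out, prof$kappa^2)
  branch <- classify_branch(prof$s, prof$kappa)
  new_elastica_ring(prof, d = d, A = A, lambda0 = lambda0, p = p,
                    energy = energy, branch = branch,
                    residuals = c(bc = res_bc, area = res_area,
                                  ode = if (used_shoot) 1e-12 else tol),
                    refined = used_shoot)
}

new_elastica_ring <- function(profile, d, A, lambda0, p, energy, branch,
                              residuals, refined) {
  structure(list(profile = profile, d = d, A = A, lambda0 = lambda0, p = p,
                 energy = energy, branch = branch, residuals = residuals,
                 refined = refined),
            class = "elastica_ring")
}

# AP reflection of a half-ring solution: x -> d - x composed with arclength
# relabeling s -> 1 - s; curvature profile maps to kappa(1 - s).
reflect_solution <- function(sol) {
  pr <- sol$profile
  n <- nrow(pr)
  idx <- rev(seq_len(n))
  prof <- tibble::tibble(
    s = pr$s,
    kappa = pr$kappa[idx],
    theta = -pr$theta[idx],
    x = sol$d - pr$x[idx],
    y = pr$y[idx],
    area_cum = sol$A - pr$area_cum[idx])
  new_elastica_ring(prof, d = sol$d, A = sol$A,
                    lambda0 = sol$lambda0, p = sol$p, energy = sol$energy,
                    branch = sol$branch, residuals = sol$residuals,
                    refined = sol$refined)
}

# label a branch from its curvature profile on the half-ring
classify_branch <- function(s, kappa) {
  if (stats::sd(kappa) < 1e-6) return("circle")
  n <- length(kappa)
  sym_dist <- sqrt(mean((kappa - rev(kappa))^2)) / sqrt(mean(kappa^2))
  k_lobes <- count_lobes(kappa)
  if (sym_dist < 1e-3) {
    if (k_lobes > 4L) return("higher-mode")
    return(sprintf("symmetric-%d-lobe", k_lobes))
  }
  if (k_lobes > 4L) return("higher-mode")
  "asymmetric"
}

# lobe number = dominant Fourier harmonic of the curvature over the full
# (mirrored, periodic) ring
count_lobes <- function(kappa) {
  full <- c(kappa, rev(kappa)[-1L])
  full <- full[-length(full)]                     # one period
  if (diff(range(full)) < 1e-10) return(0L)
  co <- Mod(stats::fft(full - mean(full)))[2:9]   # harmonics 1..8
  which.max(co)
}

#' Bending energy of a planar ring solution
#'
#' `E = (1/2) * integral of kappa^2` over the full ring, which by half-ring
#' symmetry equals the integral of `kappa(s)^2` over `s` in `[0, 1]`.  The
#' circle attains the lower bound `pi^2`.
#'
#' @param sol An `elastica_ring` solution.
#' @return Dimensionless bending energy.
#' @export
ring_energy <- function(sol) {
  stopifnot(inherits(sol, "elastica_ring"))
  sol$energy
}

#' @export
print.elastica_ring <- function(x, ...) {
  cat(sprintf(
    "<elastica_ring> branch %s | d = %.5f, A = %.5f | E = %.6f | lambda0 = %.4f, p = %.4f\n",
    x$branch, x$d, x$A, x$energy, x$lambda0, x$p))
  invisible(x)
}
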