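# Fourier-parameterized closed rings confined to a sphere or ellipsoid:
# evaluation of length, enclosed cap-side area and bending energy, and
# penalty-based constrained minimization.
#
# A ring is a closed curve in surface coordinates
#   u(t) = u0 + sum_k (au_k cos kt + bu_k sin kt)
#   v(t) = t + v0 + sum_k (av_k cos kt + bv_k sin kt),    t in [0, 2pi)
# winding once around the pole axis, expanded in n_modes harmonics.
# Coefficients are packed as c(u0, au, bu, v0, av, bv).

n_coeffs <- function(n_modes) 2L * (1L + 2L * n_modes)

ring_coeffs_circle <- function(u_lat, n_modes = 6L) {
  k <- n_coeffs(n_modes)
  co <- numeric(k)
  co[1L] <- u_lat
  co
}

unpack_coeffs <- function(coeffs, n_modes) {
  nb <- 1L + 2L * n_modes
  list(u = coeffs[seq_len(nb)], v = coeffs[nb + seq_len(nb)])
}

# Fourier basis matrices at sample parameters t: value, first and second
# derivative.  Columns: (const, cos kt ..., sin kt ...).
fourier_basis <- function(t, n_modes) {
  K <- outer(t, seq_len(n_modes))
  B <- cbind(1, cos(K), sin(K))
  kk <- rep(seq_len(n_modes), 2L)
  Bd <- cbind(0, -sin(K) %*% diag(seq_len(n_modes), n_modes),
              cos(K) %*% diag(seq_len(n_modes), n_modes))
  Bdd <- cbind(0, -cos(K) %*% diag(seq_len(n_modes)^2, n_modes),
               -sin(K) %*% diag(seq_len(n_modes)^2, n_modes))
  list(B = B, Bd = Bd, Bdd = Bdd)
}

ring_samples_uv <- function(coeffs, n_modes, basis, t) {
  cf <- unpack_coeffs(coeffs, n_modes)
  list(
    U = as.numeric(basis$B %*% cf$u),
    U1 = as.numeric(basis$Bd %*% cf$u),
    U2 = as.numeric(basis$Bdd %*% cf$u),
    V = t + as.numeric(basis$B %*% cf$v),
    V1 = 1 + as.numeric(basis$Bd %*% cf$v),
    V2 = as.numeric(basis$Bdd %*% cf$v))
}

# Cumulative meridional area Q(u) for an axisymmetric surface (b = c),
# precomputed as a monotone spline; for triaxial surfaces Q(u, v) falls back
# to Gauss quadrature at evaluation time.
make_area_fun <- function(spec, n_grid = 4001L) {
  ax <- spec$semi_axes
  if (abs(ax[2L] - ax[3L]) < 1e-12 * ax[2L]) {
    geom <- surface_geometry(spec)
    ug <- seq(0, pi, length.out = n_grid)
    sg <- geom$sqrt_g(ug, rep(0, n_grid))
    Qg <- cumtrapz_vec(ug, sg)
    Qs <- stats::splinefun(ug, Qg, method = "natural")
    function(u, v) Qs(u)
  } else {
    geom <- surface_geometry(spec)
    function(u, v) area_from_pole(geom, u, v, 24L)
  }
}

# pointwise integrands: speed (length), energy density, area density, plus
# the 3D samples.  All quantities are per unit t; integrals are mean * 2*pi.
# `ax` = semi-axes; `area_fun` from make_area_fun().
ring_pointwise_core <- function(ax, S, area_fun, energy_kind,
                                want_frame = TRUE) {
  a <- ax[1L]; b <- ax[2L]; cc <- ax[3L]
  su <- sin(S$U); cu <- cos(S$U); sv <- sin(S$V); cv <- cos(S$V)
  U1 <- S$U1; V1 <- S$V1
  r_u1 <- -a * su;      r_u2 <- b * cu * cv;   r_u3 <- cc * cu * sv
  r_v2 <- -b * su * sv; r_v3 <- cc * su * cv
  # first derivative
  rp1 <- r_u1 * U1
  rp2 <- r_u2 * U1 + r_v2 * V1
  rp3 <- r_u3 * U1 + r_v3 * V1
  # second derivative
  U2 <- S$U2; V2 <- S$V2
  rpp1 <- -a * cu * U1^2 + r_u1 * U2
  rpp2 <- -b * su * cv * U1^2 + 2 * (-b * cu * sv) * U1 * V1 +
    (-b * su * cv) * V1^2 + r_u2 * U2 + r_v2 * V2
  rpp3 <- -cc * su * sv * U1^2 + 2 * (cc * cu * cv) * U1 * V1 +
    (-cc * su * sv) * V1^2 + r_u3 * U2 + r_v3 * V2
  sp2 <- rp1^2 + rp2^2 + rp3^2
  sp <- sqrt(sp2)
  # inward normal = -(r_u x r_v)/|.|
  nx1 <- r_u2 * r_v3 - r_u3 * r_v2
  nx2 <- r_u3 * 0 - r_u1 * r_v3
  nx3 <- r_u1 * r_v2 - r_u2 * 0
  nn <- sqrt(nx1^2 + nx2^2 + nx3^2)
  n1 <- -nx1 / nn; n2 <- -nx2 / nn; n3 <- -nx3 / nn
  # curvature vector dT/ds
  dot_ppp <- rp1 * rpp1 + rp2 * rpp2 + rp3 * rpp3
  kv1 <- (rpp1 * sp2 - rp1 * dot_ppp) / sp2^2
  kv2 <- (rpp2 * sp2 - rp2 * dot_ppp) / sp2^2
  kv3 <- (rpp3 * sp2 - rp3 * dot_ppp) / sp2^2
  k_n <- kv1 * n1 + kv2 * n2 + kv3 * n3
  # binormal = n_in x tangent
  t1 <- rp1 / sp; t2 <- rp2 / sp; t3 <- rp3 / sp
  b1 <- n2 * t3 - n3 * t2
  b2 <- n3 * t1 - n1 * t3
  b3 <- n1 * t2 - n2 * t1
  k_g <- kv1 * b1 + kv2 * b2 + kv3 * b3
  k2 <- if (energy_kind == "geodesic") k_g^2 else k_g^2 + k_n^2
  out <- list(speed = sp, energy_dens = 0.5 * k2 * sp,
              area_dens = area_fun(S$U, S$V) * V1)
  if (want_frame) {
    out$r <- cbind(a * cu, b * su * cv, cc * su * sv)
    out$k_g <- k_g
    out$k_n <- k_n
  }
  out
}

ring_pointwise <- function(S, geom, energy_kind, area_fun = NULL) {
  if (is.null(area_fun)) area_fun <- make_area_fun(geom$spec)
  ring_pointwise_core(geom$spec$semi_axes, S, area_fun, energy_kind)
}

#' Evaluate a Fourier ring on a surface
#'
#' Computes the length, enclosed (pole-side) surface area, and bending
#' energy `E = (1/2) * integral of kappa^2 ds` of a closed Fourier curve
#' confined to the surface.  `energy_kind = "geodesic"` uses the geodesic
#' curvature (the intrinsic analog of the planar ring); `"full-space-curve"`
#' uses `kappa_g^2 + kappa_n^2`, which on a sphere differs only by a
#' constant.
#'
#' @param coeffs Packed Fourier coefficients (`c(u0, au, bu, v0, av, bv)`).
#' @param spec A [surface_spec()].
#' @param energy_kind `"geodesic"` or `"full-space-curve"`.
#' @param n_modes Number of harmonics per coordinate.
#' @param n_samples Quadrature samples along the curve (>= 64).
#' @param check_self_intersection Reject curves whose samples self-intersect.
#' @return An object of class `surface_ring` with fields `length`,
#'   `area_enclosed`, `energy`, `energy_kind`, `samples` (tibble with `t`,
#'   `u`, `v`, `x`, `y`, `z`, `kappa_g`, `kappa_n`), `coeffs`, `spec`.
#' @export
#' @examples
#' sp <- surface_spec("sphere", radius = 1)
#' ring <- evaluate_ring(ring_coeffs_circle(pi / 6), sp)
#' c(ring$length, ring$area_enclosed, ring$energy)
evaluate_ring <- function(coeffs, spec,
                          energy_kind = c("geodesic", "full-space-curve"),
                          n_modes = 6L, n_samples = 256L,
                          check_self_intersection = TRUE) {
  energy_kind <- match.arg(energy_kind)
  stopifnot(n_samples >= 64L)
  geom <- surface_geometry(spec)
  t <- seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)]
  basis <- fourier_basis(t, n_modes)
  S <- ring_samples_uv(coeffs, n_modes, basis, t)
  pw <- ring_pointwise(S, geom, energy_kind)
  if (check_self_intersection && ring_self_intersects(pw$r)) {
    rlang::abort("sampled ring self-intersects",
                 class = "morphoring_self_intersecting")
  }
  structure(list(
    coeffs = coeffs, n_modes = n_modes, spec = spec,
    energy_kind = energy_kind,
    length = mean(pw$speed) * 2 * pi,
    area_enclosed = mean(pw$area_dens) * 2 * pi,
    energy = mean(pw$energy_dens) * 2 * pi,
    samples = tibble::tibble(
      t = t, u = S$U, v = S$V,
      x = pw$r[, 1L], y = pw$r[, 2L], z = pw$r[, 3L],
      kappa_g = pw$k_g, kappa_n = pw$k_n),
    anchors = NULL),
    class = "surface_ring")
}

#' @export
print.surface_ring <- function(x, ...) {
  cat(sprintf(
    "<surface_ring> %s | L = %.5f, A = %.5f, E(%s) = %.5f\n",
    x$spec$kind, x$length, x$area_enclosed, x$energy_kind, x$energy))
  invisible(x)
}

# closeness test between non-adjacent sampled segments
ring_self_intersects <- function(r, guard = 8L) {
  m <- nrow(r)
  seg <- sqrt(rowSums((r[c(2:m, 1L), ] - r)^2))
  thr <- 0.5 * stats::median(seg)
  D <- as.matrix(stats::dist(r))
  idx <- abs(outer(seq_len(m), seq_len(m), "-"))
  idx <- pmin(idx, m - idx)
  any(D[idx > guard] < thr)
}

#' Minimize the bending energy of a surface-confined ring
#'
#' Quasi-Newton minimization over Fourier coefficients with quadratic
#' penalties for the length and enclosed-area constraints and (optionally)
#' hard position anchors for the material points at `t = 0` and `t = pi`,
#' ramped over a fixed number of continuation stages.
#'
#' @param spec A [surface_spec()].
#' @param L_target,A_target Length and enclosed-area constraints;
#'   `A_target = NULL` leaves the enclosed area unconstrained (relaxed
#'   configuration).
#' @param anchors Optional 2 x 3 matrix of anchor positions for the marked
#'   material points at `t = 0` and `t = pi` (each row must lie on the
#'   surface), or `NULL` for no anchors.
#' @param energy_kind As in [evaluate_ring()].
#' @param init Starting coefficients; default is the geodesic circle whose
#'   cap has area `A_target`.
#' @param perturb Amplitude of a random harmonic perturbation added to the
#'   start (used for multi-start exploration of degenerate minima).
#' @param n_modes,n_samples As in [evaluate_ring()].
#' @param n_stages Penalty continuation stages.
#' @param mu0 Initial penalty weight.
#' @param maxit BFGS iterations per stage.
#' @param constraint_tol Relative constraint tolerance demanded of the
#'   returned ring.
#' @return A `surface_ring` (see [evaluate_ring()]) with an added
#'   `constraint_residuals` field.
#' @export
minimize_surface_ring <- function(spec, L_target, A_target, anchors = NULL,
                                  energy_kind = c("geodesic",
                                                  "full-space-curve"),
                                  init = NULL, perturb = 0,
                                  n_modes = 6L, n_samples = 192L,
                                  n_stages = 5L, mu0 = 10, maxit = 200L,
                                  constraint_tol = 1e-6) {
  energy_kind <- match.arg(energy_kind)
  geom <- surface_geometry(spec)
  free_area <- is.null(A_target)
  if (free_area) A_target <- NA_real_
  stopifnot(L_target > 0, free_area || A_target > 0)
  if (!is.null(anchors)) {
    anchors <- as.matrix(anchors)
    stopifnot(nrow(anchors) == 2L, ncol(anchors) == 3L)
    if (max(abs(geom$implicit(anchors))) > 1e-6) {
      rlang::abort("anchor positions must lie on the surface",
                   class = "morphoring_infeasible")
    }
  }
  t <- seq(0, 2 * pi, length.out = n_samples + 1L)[-(n_samples + 1L)]
  basis <- fourier_basis(t, n_modes)
  if (is.null(init)) {
    u_init <- if (free_area) latitude_for_length(geom, L_target)
              else cap_colatitude(geom, A_target)
    init <- ring_coeffs_circle(u_init, n_modes)
  }
  co <- init
  if (perturb > 0) {
    nb <- 1L + 2L * n_modes
    amp <- perturb * co[1L]
    wig <- function() {
      w <- numeric(nb)
      w[1L + seq_len(4L)] <- amp * stats::rnorm(4L) / seq_len(4L)      # cos
      w[1L + n_modes + seq_len(4L)] <- amp * stats::rnorm(4L) / seq_len(4L)
      w
    }
    co[seq_len(nb)] <- co[seq_len(nb)] + wig()
    co[nb + seq_len(nb)] <- co[nb + seq_len(nb)] + 0.3 * wig()
  }
  scale_L <- L_target
  ax <- spec$semi_axes
  area_fun <- make_area_fun(spec)
  ww <- 2 * pi / n_samples
  i_anchor <- c(1L, n_samples %/% 2L + 1L)
  obj_terms <- function(coeffs) {
    S <- ring_samples_uv(coeffs, n_modes, basis, t)
    pw <- ring_pointwise_core(ax, S, area_fun, energy_kind,
                              want_frame = !is.null(anchors))
    E <- sum(pw$energy_dens) * ww
    L <- sum(pw$speed) * ww
    A <- sum(pw$area_dens) * ww
    anc <- 0
    if (!is.null(anchors)) {
      anc <- sum((pw$r[i_anchor[1L], ] - anchors[1L, ])^2 +
                   (pw$r[i_anchor[2L], ] - anchors[2L, ])^2) / scale_L^2
    }
    list(E = E, L = L, A = A, anc = anc, S = S)
  }
  # gradient: pointwise partials by central differences in the six sampled
  # slots (U, U', U'', V, V', V''), chained through the Fourier basis
  obj_grad <- function(coeffs, mu, lam = c(L = 0, A = 0)) {
    S <- ring_samples_uv(coeffs, n_modes, basis, t)
    slots <- c("U", "U1", "U2", "V", "V1", "V2")
    partials <- list()
    for (sl in slots) {
      eps <- 1e-6 * (1 + max(abs(S[[sl]])))
      Sp <- S; Sp[[sl]] <- Sp[[sl]] + eps
      Sm <- S; Sm[[sl]] <- Sm[[sl]] - eps
      fp <- ring_pointwise_core(ax, Sp, area_fun, energy_kind, FALSE)
      fm <- ring_pointwise_core(ax, Sm, area_fun, energy_kind, FALSE)
      partials[[sl]] <- list(
        E = (fp$energy_dens - fm$energy_dens) / (2 * eps),
        L = (fp$speed - fm$speed) / (2 * eps),
        A = (fp$area_dens - fm$area_dens) / (2 * eps))
    }
    chain <- function(which) {
      gu <- crossprod(basis$B, partials$U[[which]]) +
        crossprod(basis$Bd, partials$U1[[which]]) +
        crossprod(basis$Bdd, partials$U2[[which]])
      gv <- crossprod(basis$B, partials$V[[which]]) +
        crossprod(basis$Bd, partials$V1[[which]]) +
        crossprod(basis$Bdd, partials$V2[[which]])
      ww * c(gu, gv)
    }
    ot <- obj_terms(coeffs)
    cL <- ot$L / L_target - 1
    cA <- if (free_area) 0 else ot$A / A_target - 1
    g <- chain("E") +
      (2 * mu * cL - lam["L"]) / L_target * chain("L")
    if (!free_area) {
      g <- g + (2 * mu * cA - lam["A"]) / A_target * chain("A")
    }
    if (!is.null(anchors)) {
      pwf <- ring_pointwise_core(ax, S, area_fun, energy_kind, TRUE)
      nb <- 1L + 2L * n_modes
      ganc <- numeric(2L * nb)
      for (j in 1:2) {
        i <- i_anchor[j]
        dv <- geom$derivs(S$U[i], S$V[i])
        dres <- 2 * (pwf$r[i, ] - anchors[j, ]) / scale_L^2
        dU <- sum(dres * dv$r_u)
        dV <- sum(dres * dv$r_v)
        ganc[seq_len(nb)] <- ganc[seq_len(nb)] + dU * basis$B[i, ]
        ganc[nb + seq_len(nb)] <- ganc[nb + seq_len(nb)] + dV * basis$B[i, ]
      }
      g <- g + mu * ganc
    }
    as.numeric(g)
  }
  # augmented Lagrangian on the two scalar constraints; anchors stay as a
  # ramped quadratic penalty (they are satisfied to ~1e-9 by the quadratic
  # alone since the optimum sits at the anchor)
  mu <- mu0
  lam <- c(L = 0, A = 0)
  for (stage in seq_len(n_stages)) {
    fn <- function(coeffs) {
      ot <- obj_terms(coeffs)
      cL <- ot$L / L_target - 1
      cA <- if (free_area) 0 else ot$A / A_target - 1
      ot$E - lam["L"] * cL - lam["A"] * cA +
        mu * (cL^2 + cA^2 + ot$anc)
    }
    gr <- function(coeffs) obj_grad(coeffs, mu, lam)
    opt <- stats::optim(co, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-12))
    co <- opt$par
    ot <- obj_terms(co)
    cL <- ot$L / L_target - 1
    cA <- if (free_area) 0 else ot$A / A_target - 1
    lam <- lam - 2 * mu * c(L = cL, A = cA)
    if (max(abs(c(cL, cA))) > 1e-4 || stage < 3L) mu <- mu * 12
  }
  ring <- evaluate_ring(co, spec, energy_kind, n_modes = n_modes,
                        n_samples = max(n_samples, 256L),
                        check_self_intersection = TRUE)
  resid <- c(length = abs(ring$length / L_target - 1),
             area = if (free_area) 0
                    else abs(ring$area_enclosed / A_target - 1))
  if (!is.null(anchors)) {
    i0 <- 1L
    ipi <- nrow(ring$samples) %/% 2L + 1L
    pr <- as.matrix(ring$samples[c(i0, ipi), c("x", "y", "z")])
    resid <- c(resid, anchor = max(sqrt(rowSums((pr - anchors)^2))) / scale_L)
  }
  if (max(resid[c("length", "area")]) > 100 * constraint_tol) {
    rlang::abort(sprintf(
      "surface ring minimization did not meet constraints (length %.2e, area %.2e rel.)",
      resid["length"], resid["area"]), class = "morphoring_no_convergence")
  }
  ring$constraint_residuals <- resid
  ring$anchors <- anchors
  ring
}

# colatitude of the latitude circle with prescribed circumference
latitude_for_length <- function(geom, L_target) {
  ax <- geom$spec$semi_axes
  circ <- function(u) {
    t <- seq(0, 2 * pi, length.out = 257L)[-257L]
    P <- geom$embed(rep(u, 256L), t)
    sum(sqrt(rowSums((P[c(2:256, 1L), ] - P)^2)))
  }
  stats::uniroot(function(u) circ(u) - L_target, c(1e-3, pi / 2),
                 tol = 1e-10)$root
}

# colatitude of the pole-side cap with prescribed area (bisection)
cap_colatitude <- function(geom, A_target) {
  f <- function(u) area_from_pole(geom, u, 0) * 2 * pi - A_target
  lo <- 1e-3; hi <- pi - 1e-3
  if (f(hi) < 0) {
    rlang::abort("A_target exceeds the surface area reachable by a cap",
                 class = "morphoring_infeasible")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Signed orientation statistic of a surface ring
#'
#' Third-harmonic descriptor of the ring's radial profile about its
#' centroid, measured in a tangent-plane frame: the first axis is the
#' in-plane direction toward the first anchor (for anchored rings, so that
#' exchanging the anchors flips the phase by `pi`), or the projection of
#' the AP (+x) direction otherwise.  The returned scalar is the real part
#' of the complex third-harmonic coefficient (normalized by the mean
#' radius): it vanishes for circles, its sign distinguishes the two
#' orientations of a triangular ring relative to the marked points, and it
#' flips under the reflection exchanging them.  The attribute
#' `"magnitude"` carries the harmonic magnitude and `"imag"` the
#' mirror-breaking component.
#'
#' @param ring A `surface_ring`.
#' @return Signed scalar with attributes `magnitude` and `imag`.
#' @export
orientation_statistic <- function(ring) {
  stopifnot(inherits(ring, "surface_ring"))
  P <- as.matrix(ring$samples[, c("x", "y", "z")])
  ctr <- colMeans(P)
  geom <- surface_geometry(ring$spec)
  # tangent frame at the surface point nearest the centroid
  uv <- nearest_surface_uv(geom, ctr)
  n <- as.numeric(geom$normal(uv[1L], uv[2L]))
  ref <- if (!is.null(ring$anchors)) {
    as.numeric(ring$anchors[1L, ]) - ctr
  } else {
    c(1, 0, 0)
  }
  e1 <- ref - sum(ref * n) * n
  if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2L] * e1[3L] - n[3L] * e1[2L],
          n[3L] * e1[1L] - n[1L] * e1[3L],
          n[1L] * e1[2L] - n[2L] * e1[1L])
  Q <- sweep(P, 2L, ctr)
  xi <- Q %*% e1; eta <- Q %*% e2
  rho <- sqrt(xi^2 + eta^2)
  phi <- atan2(eta, xi)
  ord <- order(phi)
  phi <- phi[ord]; rho <- rho[ord]
  # trapezoid weights on the circle
  dphi <- diff(c(phi, phi[1L] + 2 * pi))
  w <- (dphi + c(dphi[length(dphi)], dphi[-length(dphi)])) / 2
  z3 <- sum(rho * exp(-3i * phi) * w) / pi
  stat <- Re(z3) / mean(rho)
  attr(stat, "magnitude") <- Mod(z3) / mean(rho)
  attr(stat, "imag") <- Im(z3) / mean(rho)
  stat
}

# project a 3D point to surface parameters (Gauss-Newton on (u, v))
nearest_surface_uv <- function(geom, p) {
  u <- acos(max(-1, min(1, p[1L] / geom$spec$semi_axes[1L])))
  v <- atan2(p[3L] / geom$spec$semi_axes[3L], p[2L] / geom$spec$semi_axes[2L])
  for (it in 1:30) {
    r <- as.numeric(geom$embed(u, v))
    dv <- geom$derivs(u, v)
    J <- cbind(as.numeric(dv$r_u), as.numeric(dv$r_v))
    rhs <- crossprod(J, p - r)
    H <- crossprod(J)
    step <- tryCatch(solve(H, rhs), error = function(e) NULL)
    if (is.null(step)) break
    u <- u + step[1L]; v <- v + step[2L]
    if (max(abs(step)) < 1e-12) break
  }
  c(u, v)
}
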