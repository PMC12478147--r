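# Symmetry transforms of surface rings, translated-ring initialization, and
# the genetic-perturbation scenario drivers.

#' Symmetry images of ring coefficients
#'
#' For anchors placed in the `v = 0, pi` plane, the constraint set is
#' invariant under the mirror across the plane containing the anchors and
#' the pole axis (`v -> -v` composed with parameter reversal) and under the
#' anchor swap (`pi` rotation about the pole axis composed with the
#' relabeling `t -> t + pi`).  These maps send stationary rings to
#' stationary rings of exactly equal energy and are used to enumerate the
#' degenerate minima.
#'
#' @param coeffs Packed Fourier coefficients.
#' @param which `"mirror"`, `"swap"`, or `"both"`.
#' @param n_modes Number of harmonics.
#' @return Transformed coefficient vector.
#' @export
ring_coeffs_transform <- function(coeffs, which = c("mirror", "swap", "both"),
                                  n_modes = 6L) {
  which <- match.arg(which)
  nb <- 1L + 2L * n_modes
  cu <- coeffs[seq_len(nb)]; cv <- coeffs[nb + seq_len(nb)]
  k <- seq_len(n_modes)
  if (which %in% c("swap", "both")) {
    # pi rotation about the pole axis composed with the relabeling
    # t -> t + pi: the two pi shifts in v cancel, the harmonics pick up
    # (-1)^k, and the anchors are exchanged as material points
    sgn <- (-1)^k
    cu[1L + k] <- cu[1L + k] * sgn
    cu[1L + n_modes + k] <- cu[1L + n_modes + k] * sgn
    cv[1L + k] <- cv[1L + k] * sgn
    cv[1L + n_modes + k] <- cv[1L + n_modes + k] * sgn
  }
  if (which %in% c("mirror", "both")) {
    # t -> -t, v -> -v: u(t) -> u(-t), v(t) -> -v(-t)
    cu[1L + n_modes + k] <- -cu[1L + n_modes + k]       # u sines flip
    cv[1L] <- -cv[1L]
    cv[1L + k] <- -cv[1L + k]                           # v cosines flip
  }
  c(cu, cv)
}

# least-squares Fourier fit of sampled (u, v) paths (v minus the winding t)
ring_coeffs_fit <- function(u_s, v_s, t, n_modes = 6L) {
  B <- fourier_basis(t, n_modes)$B
  cu <- qr.solve(B, u_s)
  cv <- qr.solve(B, v_s - t)
  c(cu, cv)
}

# initial coefficients for a ring of angular radius u_ring whose center is
# translated by beta toward dorsal (+z) along the sagittal plane.  The ring
# is constructed as a small circle on the unit sphere of directions and the
# spherical (u, v) parameters are transplanted onto the surface chart; this
# gives a smooth star-shaped start with v(t) = t + pi/2 uniform (material
# point t = 0 at the dorsal sagittal crossing).
translated_ring_coeffs <- function(spec, u_ring, beta, n_modes = 6L,
                                   n_fit = 512L) {
  tt <- seq(0, 2 * pi, length.out = n_fit + 1L)[-(n_fit + 1L)]
  ctr <- c(cos(beta), 0, sin(beta))
  e1 <- c(-sin(beta), 0, cos(beta))       # dorsal direction at the center
  e2 <- c(0, -1, 0)
  P <- outer(rep(1, n_fit), ctr * cos(u_ring)) +
    sin(u_ring) * (outer(cos(tt), e1) + outer(sin(tt), e2))
  u_s <- acos(pmax(-1, pmin(1, P[, 1L])))
  v_s <- atan2(P[, 3L], P[, 2L])
  ord <- order(v_s)
  vs <- v_s[ord]; us <- u_s[ord]
  vq <- (tt + pi / 2 + pi) %% (2 * pi) - pi
  uq <- stats::approx(c(vs[length(vs)] - 2 * pi, vs, vs[1L] + 2 * pi),
                      c(us[length(us)], us, us[1L]), xout = vq)$y
  B <- fourier_basis(tt, n_modes)$B
  cu <- qr.solve(B, uq)
  cv <- numeric(1L + 2L * n_modes)
  cv[1L] <- pi / 2
  c(cu, cv)
}

# radial projection of 3D points onto the ellipsoid, in (u, v) parameters
xyz_to_uv <- function(spec, P) {
  ax <- spec$semi_axes
  q <- sweep(P, 2L, ax, "/")
  q <- q / sqrt(rowSums(q^2))
  u <- acos(pmax(-1, pmin(1, q[, 1L])))
  v <- atan2(q[, 3L], q[, 2L])
  cbind(u, v)
}

# arc length along the sagittal ellipse (x = a cos t, z = c sin t) from the
# posterior pole to parametric angle theta, and its inverse
sagittal_arc <- function(spec, theta) {
  ax <- spec$semi_axes
  vapply(theta, function(th) {
    if (th == 0) return(0)
    sign(th) * stats::integrate(function(t)
      sqrt(ax[1L]^2 * sin(t)^2 + ax[3L]^2 * cos(t)^2),
      0, abs(th), rel.tol = 1e-12)$value
  }, numeric(1))
}

sagittal_arc_inv <- function(spec, s) {
  vapply(s, function(si) {
    if (si == 0) return(0)
    sign(si) * stats::uniroot(function(th)
      sagittal_arc(spec, th) - abs(si),
      c(0, pi), tol = 1e-12)$root
  }, numeric(1))
}

#' Specify a genetic-perturbation scenario
#'
#' Encodes the boundary conditions the surrounding tissues impose on the
#' hindgut ring in wildtype and in the three classic mutant backgrounds:
#' `WT` (area reduced, ring translated dorsally), `fog` (no apical
#' constriction: area kept, ring stays at the pole), `bcd_osk` (area
#' reduced, translation preserved by dorsal contraction, increased AP
#' diameter), and `bcd_osk_spz` (area reduced, no translation, no diameter
#' constraint).
#'
#' @param name One of `"WT"`, `"fog"`, `"bcd_osk"`, `"bcd_osk_spz"`.
#' @param u_ring Initial ring colatitude on the surface (radians from the
#'   posterior pole).
#' @param translation Dorsal translation of the ring along the sagittal
#'   ellipse, as a fraction of the initial pole-to-crossing arc (so 1 puts
#'   the ventral crossing exactly at the pole).
#' @param area_factor Enclosed-area multiplier applied by midgut
#'   invagination, relative to the relaxed translated ring.
#' @param d_factor Multiplier on the anchor arc separation (the AP
#'   diameter).
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("fog")
scenario_spec <- function(name = c("WT", "fog", "bcd_osk", "bcd_osk_spz"),
                          u_ring = 0.55, translation = NULL,
                          area_factor = NULL, d_factor = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    WT = list(translation = 0.8, area_factor = 0.85, d_factor = 1,
              anchored = TRUE),
    fog = list(translation = 0, area_factor = 1, d_factor = 1,
               anchored = TRUE),
    bcd_osk = list(translation = 0.8, area_factor = 0.85, d_factor = 1.25,
                   anchored = TRUE),
    bcd_osk_spz = list(translation = 0, area_factor = 0.85, d_factor = 1,
                       anchored = FALSE))
  structure(list(
    name = name, u_ring = u_ring,
    translation = if (is.null(translation)) defaults$translation
                  else translation,
    area_factor = if (is.null(area_factor)) defaults$area_factor
                  else area_factor,
    d_factor = if (is.null(d_factor)) defaults$d_factor else d_factor,
    anchored = defaults$anchored),
    class = "scenario_spec")
}

#' Run a genetic-perturbation scenario
#'
#' Minimizes the ring bending energy under the boundary conditions of the
#' scenario on the given surface and classifies the resulting shape.
#'
#' @param scenario A [scenario_spec()] or scenario name.
#' @param spec A [surface_spec()]; default the 2.5:1:1 ellipsoid.
#' @param perturb Random harmonic perturbation of the start (set > 0 to
#'   explore degenerate orientations; each run draws from the current RNG
#'   state).
#' @param energy_kind,n_modes As in [minimize_surface_ring()].
#' @param max_tries Retries with a fresh perturbation draw if a run fails
#'   (self-intersection or non-convergence).
#' @param n_stages,maxit Optimizer effort per stage (see
#'   [minimize_surface_ring()]).
#' @param relaxed Optional precomputed relaxed ring (stage 1) from a
#'   previous run of the same scenario, to skip recomputing it across
#'   multi-start repetitions.
#' @param ... Passed to [minimize_surface_ring()].
#' @return A `surface_ring` with added fields `scenario`, `shape_class`
#'   (`"circle"`, `"keyhole"`, or `"buckled"`), `orientation` (the
#'   [orientation_statistic()]), and `circle_energy` (geodesic-circle
#'   reference energy at the same constraints, when defined).
#' @export
run_scenario <- function(scenario, spec = surface_spec("ellipsoid",
                                                       c(2.5, 1, 1)),
                         perturb = 0.15, energy_kind = "geodesic",
                         n_modes = 6L, max_tries = 3L, n_stages = 7L,
                         maxit = 300L, relaxed = NULL, ...) {
  if (is.character(scenario)) scenario <- scenario_spec(scenario)
  stopifnot(inherits(scenario, "scenario_spec"))
  geom <- surface_geometry(spec)
  u0 <- scenario$u_ring
  ring0 <- evaluate_ring(ring_coeffs_circle(u0, n_modes), spec,
                         energy_kind, n_modes = n_modes,
                         check_self_intersection = FALSE)
  L_t <- ring0$length
  anchors <- NULL
  init <- NULL
  if (scenario$anchored) {
    # anchors at fixed arc distances along the sagittal ellipse: the ring's
    # crossings sit at +/- s0 * d_factor about the translated center
    s0 <- sagittal_arc(spec, u0)
    s_c <- scenario$translation * s0
    s_anch <- c(s_c + s0 * scenario$d_factor, s_c - s0 * scenario$d_factor)
    th <- sagittal_arc_inv(spec, s_anch)
    anchors <- rbind(
      geom$embed(abs(th[1L]), ifelse(th[1L] >= 0, pi / 2, -pi / 2)),
      geom$embed(abs(th[2L]), ifelse(th[2L] >= 0, pi / 2, -pi / 2)))
    init <- translated_ring_coeffs(spec, u0 * scenario$d_factor,
                                   sagittal_arc_inv(spec, s_c), n_modes)
  } else {
    init <- ring_coeffs_circle(u0, n_modes)
    init[1L + 2L * n_modes + 1L] <- pi / 2      # v0: t=0 at dorsal crossing
  }
  # stage 1: relax under length + anchors only (germ-band translation);
  # the relaxed enclosed area is the reference the midgut then contracts.
  # A relaxed ring from a previous run of the same scenario can be reused.
  if (is.null(relaxed)) {
    relaxed <- minimize_surface_ring(spec, L_t, A_target = NULL,
                                     anchors = anchors,
                                     energy_kind = energy_kind, init = init,
                                     perturb = 0, n_modes = n_modes,
                                     n_stages = n_stages, maxit = maxit, ...)
  }
  A_t <- scenario$area_factor * relaxed$area_enclosed
  ring <- NULL
  if (abs(scenario$area_factor - 1) < 1e-12) {
    ring <- relaxed
    ring$constraint_residuals["area"] <- 0
  } else {
    for (k in seq_len(max_tries)) {
      ring <- tryCatch(
        minimize_surface_ring(spec, L_t, A_t, anchors = anchors,
                              energy_kind = energy_kind,
                              init = relaxed$coeffs,
                              perturb = perturb, n_modes = n_modes,
                              n_stages = n_stages, maxit = maxit, ...),
        error = function(e) NULL)
      if (!is.null(ring)) break
    }
  }
  if (is.null(ring)) {
    rlang::abort(sprintf("scenario %s failed to converge", scenario$name),
                 class = "morphoring_no_convergence")
  }
  os <- orientation_statistic(ring)
  # reference circle at the same constraints: exists when the unanchored
  # geodesic circle satisfies both (fog: it does by construction)
  circ_E <- NA_real_
  u_cap <- tryCatch(cap_colatitude(geom, A_t), error = function(e) NA)
  if (is.finite(u_cap)) {
    rc <- evaluate_ring(ring_coeffs_circle(u_cap, n_modes), spec,
                        energy_kind, n_modes = n_modes,
                        check_self_intersection = FALSE)
    if (abs(rc$length / L_t - 1) < 0.02) circ_E <- rc$energy
  }
  mag <- attr(os, "magnitude")
  cls <- if (mag < 1e-3 && is.finite(circ_E) &&
               abs(ring$energy / circ_E - 1) < 0.01) "circle"
         else if (mag >= 0.01) "keyhole"
         else "buckled"
  ring$scenario <- scenario
  ring$shape_class <- cls
  ring$orientation <- os
  ring$circle_energy <- circ_E
  ring$relaxed <- relaxed
  ring
}

#' Enumerate the degenerate minima of an anchored surface ring
#'
#' Multi-starts [minimize_surface_ring()] until a clearly buckled minimum is
#' found, then re-minimizes from the three symmetry images of its
#' coefficients (sagittal mirror, anchor swap, both), yielding the four
#' degenerate minima the constraint symmetry group predicts.
#'
#' @inheritParams minimize_surface_ring
#' @param n_starts Random starts used to locate the first buckled minimum.
#' @param min_magnitude Orientation-statistic magnitude above which a
#'   minimum counts as buckled.
#' @return A list of four `surface_ring` objects (converged independently),
#'   or fewer if runs fail.
#' @export
degenerate_minima <- function(spec, L_target, A_target, anchors,
                              energy_kind = "geodesic", n_modes = 6L,
                              n_starts = 8L, min_magnitude = 0.03, ...) {
  base <- NULL
  best_mag <- 0
  for (k in seq_len(n_starts)) {
    r <- tryCatch(
      minimize_surface_ring(spec, L_target, A_target, anchors = anchors,
                            energy_kind = energy_kind, n_modes = n_modes,
                            perturb = 0.35, ...),
      error = function(e) NULL)
    if (is.null(r)) next
    mag <- attr(orientation_statistic(r), "magnitude")
    if (mag > best_mag) { base <- r; best_mag <- mag }
    if (best_mag >= 2 * min_magnitude) break
  }
  if (is.null(base) || best_mag < min_magnitude) {
    rlang::abort("no buckled minimum found by multi-start",
                 class = "morphoring_no_convergence")
  }
  images <- c("mirror", "swap", "both")
  out <- list(base)
  for (im in images) {
    co <- ring_coeffs_transform(base$coeffs, im, n_modes)
    # the image already satisfies the constraints, so polish locally with
    # the penalty at full strength instead of re-ramping (a fresh ramp
    # would let the shape wander along the nearly flat phase valley)
    r <- tryCatch(
      minimize_surface_ring(spec, L_target, A_target, anchors = anchors,
                            energy_kind = energy_kind, n_modes = n_modes,
                            init = co, perturb = 0, n_stages = 2L,
                            mu0 = 10 * 12^4, ...),
      error = function(e) NULL)
    if (!is.null(r)) out[[length(out) + 1L]] <- r
  }
  out
}
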