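# Sphere/ellipsoid geometry for surface-confined rings.
#
# The embryo surface is an ellipsoid with semi-axes (a, b, c), parameterized
# by a colatitude-like angle u measured from the +x pole (the posterior pole
# of the long axis) and an azimuth v about the x axis:
#   r(u, v) = (a cos u, b sin u cos v, c sin u sin v).
# All first and second derivatives are analytic, so lengths, curvatures and
# the area quadrature need no numerical differentiation.

#' Specify a sphere or ellipsoid surface
#'
#' @param kind `"sphere"` or `"ellipsoid"`.
#' @param semi_axes Numeric of length 3 `(a, b, c)`; for a sphere give
#'   `radius` instead.  The default ellipsoid has the embryo-like aspect
#'   ratio 2.5:1:1.
#' @param radius Sphere radius (used when `kind = "sphere"`).
#' @return An object of class `surface_spec`.
#' @export
#' @examples
#' surface_spec("ellipsoid", semi_axes = c(2.5, 1, 1))
#' surface_spec("sphere", radius = 1)
surface_spec <- function(kind = c("ellipsoid", "sphere"),
                         semi_axes = c(2.5, 1, 1), radius = 1) {
  kind <- match.arg(kind)
  if (kind == "sphere") semi_axes <- rep(radius, 3L)
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(!is.finite(semi_axes)) ||
      any(semi_axes <= 0)) {
    rlang::abort("all semi-axes must be positive and finite",
                 class = "morphoring_degenerate_surface")
  }
  structure(list(kind = kind, semi_axes = semi_axes), class = "surface_spec")
}

#' @export
print.surface_spec <- function(x, ...) {
  cat(sprintf("<surface_spec> %s, semi-axes (%.4g, %.4g, %.4g)\n",
              x$kind, x$semi_axes[1L], x$semi_axes[2L], x$semi_axes[3L]))
  invisible(x)
}

#' Eccentricity of the sagittal cross-section
#'
#' The sagittal section of the embryo ellipsoid (through the AP and
#' dorsoventral axes) is an ellipse with semi-axes `a` and `c`; its
#' eccentricity `sqrt(1 - (c/a)^2)` parameterizes the arclength coordinate
#' used to reference contour positions.  For the 2.5:1:1 embryo this is
#' 0.92 to two decimals.
#'
#' @param spec A [surface_spec()].
#' @return Eccentricity in `[0, 1)`.
#' @export
#' @examples
#' sagittal_eccentricity(surface_spec("ellipsoid", c(2.5, 1, 1)))
sagittal_eccentricity <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  ax <- spec$semi_axes
  a <- max(ax[1L], ax[3L]); cc <- min(ax[1L], ax[3L])
  sqrt(1 - (cc / a)^2)
}

#' Geometry evaluator for a surface
#'
#' Returns closures evaluating the embedding, its derivatives, the unit
#' normal, the area element and the principal curvatures at surface
#' parameters `(u, v)` (vectorized).
#'
#' @param spec A [surface_spec()].
#' @return A list of functions: `embed(u, v)` (n x 3), `derivs(u, v)` (list
#'   of `r_u`, `r_v`, `r_uu`, `r_uv`, `r_vv`), `normal(u, v)` (outward unit
#'   normal, n x 3), `sqrt_g(u, v)` (area element), `principal(u, v)`
#'   (n x 2 principal curvatures), `implicit(xyz)` (residual of the
#'   ellipsoid equation).
#' @export
surface_geometry <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  ax <- spec$semi_axes
  a <- ax[1L]; b <- ax[2L]; c_ <- ax[3L]
  embed <- function(u, v) {
    cbind(a * cos(u), b * sin(u) * cos(v), c_ * sin(u) * sin(v))
  }
  derivs <- function(u, v) {
    su <- sin(u); cu <- cos(u); sv <- sin(v); cv <- cos(v)
    list(
      r_u = cbind(-a * su, b * cu * cv, c_ * cu * sv),
      r_v = cbind(0 * u, -b * su * sv, c_ * su * cv),
      r_uu = cbind(-a * cu, -b * su * cv, -c_ * su * sv),
      r_uv = cbind(0 * u, -b * cu * sv, c_ * cu * cv),
      r_vv = cbind(0 * u, -b * su * cv, -c_ * su * sv))
  }
  normal <- function(u, v) {
    dv <- derivs(u, v)
    nr <- cross3(dv$r_u, dv$r_v)
    nr / sqrt(rowSums(nr^2))           # r_u x r_v is outward for u in (0, pi)
  }
  sqrt_g <- function(u, v) {
    dv <- derivs(u, v)
    sqrt(rowSums(cross3(dv$r_u, dv$r_v)^2))
  }
  principal <- function(u, v) {
    dv <- derivs(u, v)
    n <- -normal(u, v)      # inward normal: convex surface has positive curvature
    E <- rowSums(dv$r_u^2); FF <- rowSums(dv$r_u * dv$r_v)
    G <- rowSums(dv$r_v^2)
    L <- rowSums(dv$r_uu * n); M <- rowSums(dv$r_uv * n)
    N <- rowSums(dv$r_vv * n)
    # shape operator eigenvalues from the two fundamental forms
    H <- (E * N - 2 * FF * M + G * L) / (2 * (E * G - FF^2))
    K <- (L * N - M^2) / (E * G - FF^2)
    disc <- pmax(H^2 - K, 0)
    cbind(H + sqrt(disc), H - sqrt(disc))
  }
  implicit <- function(xyz) {
    (xyz[, 1L] / a)^2 + (xyz[, 2L] / b)^2 + (xyz[, 3L] / c_)^2 - 1
  }
  list(embed = embed, derivs = derivs, normal = normal, sqrt_g = sqrt_g,
       principal = principal, implicit = implicit, spec = spec)
}

cross3 <- function(p, q) {
  cbind(p[, 2L] * q[, 3L] - p[, 3L] * q[, 2L],
        p[, 3L] * q[, 1L] - p[, 1L] * q[, 3L],
        p[, 1L] * q[, 2L] - p[, 2L] * q[, 1L])
}

# meridional area integral Q(u, v) = int_0^u sqrt(g)(u', v) du' by fixed
# Gauss-Legendre quadrature (vectorized over samples)
area_from_pole <- function(geom, u, v, n_gauss = 24L) {
  gl <- gauss_legendre(n_gauss)
  # nodes scaled to (0, u) per sample
  M <- length(u)
  uu <- outer(u / 2, gl$x + 1)          # M x G in (0, u)
  vv <- matrix(v, M, n_gauss)
  sg <- matrix(geom$sqrt_g(as.vector(uu), as.vector(vv)), M, n_gauss)
  as.numeric((sg %*% gl$w) * u / 2)
}

# Golub-Welsch nodes/weights on [-1, 1], cached
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1L)
    beta <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1L)] <- beta
    J[cbind(i + 1L, i)] <- beta
    ev <- eigen(J, symmetric = TRUE)
    x <- ev$values
    w <- 2 * ev$vectors[1L, ]^2
    ord <- order(x)
    res <- list(x = x[ord], w = w[ord])
    cache[[key]] <<- res
    res
  }
})
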