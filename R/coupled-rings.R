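# Coupled-ring geometric model: inner and outer contours as uniform normal
# offsets of a middle ellipse of constant length or constant area.

#' Ellipse perimeter
#'
#' Perimeter of an ellipse with semimajor axis `a` and semiminor axis `b`,
#' `4 a E(e)` with `E` the complete elliptic integral of the second kind and
#' `e^2 = 1 - b^2/a^2`.
#'
#' @param a,b Semi-axes (`a >= b > 0`).
#' @return Perimeter (same units as the axes).
#' @export
#' @examples
#' ellipse_perimeter(1, 1) / (2 * pi) # 1
ellipse_perimeter <- function(a, b) {
  stopifnot(all(a >= b), all(b > 0))
  m <- 1 - (b / a)^2
  e2 <- vapply(m, function(mi) pracma::ellipke(mi)$e, numeric(1))
  4 * a * e2
}

#' Incomplete elliptic arclength of an ellipse
#'
#' `E(theta, eps)`, the incomplete elliptic integral of the second kind:
#' the arclength of a unit-semimajor-axis ellipse of eccentricity `eps` from
#' the major-axis vertex to parametric angle `theta`.  Used to express
#' contour positions along the sagittal cross-section of the embryo.
#'
#' @param theta Parametric angle(s) from the major (AP) axis, radians.
#' @param eps Eccentricity in `[0, 1)`.
#' @return Arclength value(s) `E(theta, eps)`.
#' @export
#' @examples
#' elliptic_arc(pi / 2, 0) # pi/2: circular cross-section
elliptic_arc <- function(theta, eps) {
  stopifnot(eps >= 0, eps < 1)
  vapply(theta, function(th) {
    if (th == 0) return(0)
    sgn <- sign(th)
    stats::integrate(function(t) sqrt(1 - eps^2 * sin(t)^2), 0, abs(th),
                     rel.tol = 1e-12)$value * sgn
  }, numeric(1))
}

#' Length and area of a parallel (normal offset) curve
#'
#' For a convex closed curve of length `L_mid` enclosing area `A_mid`, the
#' uniform normal offset at distance `h` has the closed forms
#' `L = L_mid + 2*pi*h`, `A = A_mid + L_mid*h + pi*h^2` (outward) and
#' `L = L_mid - 2*pi*h`, `A = A_mid - L_mid*h + pi*h^2` (inward).  The inward
#' offset self-intersects once `h` reaches the minimum radius of curvature,
#' at which point the formulas cease to describe a simple curve.
#'
#' @param L_mid,A_mid Length and enclosed area of the middle curve.
#' @param h Offset distance (>= 0).
#' @param direction `"outward"` or `"inward"`.
#' @param min_radius Optional minimum radius of curvature of the middle
#'   curve (e.g. `b^2/a` for an ellipse); if supplied, an inward offset with
#'   `h >= min_radius` raises an `morphoring_offset_too_large` error.
#' @return Named numeric vector `c(L = , A = )`.
#' @export
#' @examples
#' offset_curve_metrics(2 * pi, pi, 0.1, "outward") # circle r = 1 -> r = 1.1
offset_curve_metrics <- function(L_mid, A_mid, h,
                                 direction = c("outward", "inward"),
                                 min_radius = NULL) {
  direction <- match.arg(direction)
  stopifnot(L_mid > 0, A_mid >= 0, h >= 0)
  if (direction == "inward" && !is.null(min_radius) && h >= min_radius) {
    rlang::abort(sprintf(
      "inward offset h = %.4g reaches the minimum radius of curvature %.4g: the parallel curve self-intersects",
      h, min_radius), class = "morphoring_offset_too_large")
  }
  if (direction == "outward") {
    c(L = L_mid + 2 * pi * h, A = A_mid + L_mid * h + pi * h^2)
  } else {
    c(L = L_mid - 2 * pi * h, A = A_mid - L_mid * h + pi * h^2)
  }
}

#' Coupled-ring predictions for inner and outer contours
#'
#' Drives the offset-curve model with a time series of middle-ellipse
#' semi-axes and measured middle-to-inner / middle-to-outer distances.  In
#' `"constant-length"` mode the semi-axes are rescaled at every timepoint so
#' the middle perimeter keeps its initial value; in `"constant-area"` mode so
#' the middle area does.  Inner and outer lengths and areas then follow from
#' the parallel-curve closed forms, predicting that as the offsets grow the
#' inner metrics decrease while the outer metrics increase.
#'
#' @param states A data frame with one row per timepoint and columns
#'   `f_x` (middle semiminor axis), `f_y` (middle semimajor axis),
#'   `d_i`, `d_o` (offset distances); optionally `timepoint`.
#' @param mode `"constant-length"` or `"constant-area"`.
#' @return A tibble with per-timepoint middle/inner/outer lengths and areas
#'   (`L_mid`, `A_mid`, `L_in`, `A_in`, `L_out`, `A_out`) and the rescaled
#'   semi-axes `f_x_scaled`, `f_y_scaled`.
#' @export
#' @examples
#' st <- tibble::tibble(f_x = c(10, 9.5), f_y = c(10, 11),
#'                      d_i = c(1, 1.5), d_o = c(1, 1.5))
#' coupled_ring_predict(st, "constant-length")
coupled_ring_predict <- function(states,
                                 mode = c("constant-length", "constant-area")) {
  mode <- match.arg(mode)
  states <- tibble::as_tibble(states)
  need <- c("f_x", "f_y", "d_i", "d_o")
  if (!all(need %in% names(states))) {
    rlang::abort(paste("states must have columns", paste(need, collapse = ", ")),
                 class = "morphoring_format_error")
  }
  stopifnot(nrow(states) >= 1L, all(states$f_x > 0), all(states$f_y > 0),
            all(states$d_i >= 0), all(states$d_o >= 0))
  a <- pmax(states$f_y, states$f_x)
  b <- pmin(states$f_y, states$f_x)
  if (mode == "constant-length") {
    P <- ellipse_perimeter(a, b)
    sc <- P[1L] / P
  } else {
    Ar <- pi * a * b
    sc <- sqrt(Ar[1L] / Ar)
  }
  a <- a * sc; b <- b * sc
  L_mid <- ellipse_perimeter(a, b)
  A_mid <- pi * a * b
  min_r <- b^2 / a
  res <- purrr::pmap(
    list(L_mid, A_mid, states$d_i, states$d_o, min_r),
    function(L, A, di, do_, mr) {
      inner <- offset_curve_metrics(L, A, di, "inward", min_radius = mr)
      outer <- offset_curve_metrics(L, A, do_, "outward")
      c(L_in = unname(inner["L"]), A_in = unname(inner["A"]),
        L_out = unname(outer["L"]), A_out = unname(outer["A"]))
    })
  out <- tibble::tibble(
    timepoint = if ("timepoint" %in% names(states)) states$timepoint
                else seq_len(nrow(states)),
    f_x_scaled = b, f_y_scaled = a,
    L_mid = L_mid, A_mid = A_mid)
  dplyr::bind_cols(out, dplyr::bind_rows(lapply(res, as.list)))
}
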