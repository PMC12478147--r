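# Contour kinematics: from tracked nuclei to deforming closed contours and
# shape-metric time series.

#' Exponentially smooth nuclear tracks
#'
#' Applies an exponential moving average with coefficient
#' `alpha = 2/(window + 1)` to each spatial dimension of each track,
#' initialized at the first observation.  Tracks must be complete (present
#' at every timepoint).
#'
#' @param tracks Long-format track table with columns `track_id`,
#'   `timepoint`, `x_um`, `y_um`, `z_um`.
#' @param window EMA window size in timepoints (default 10, i.e.
#'   `alpha = 2/11`).
#' @return A tibble of the same shape with smoothed coordinates.
#' @export
#' @examples
#' tr <- tibble::tibble(track_id = 1, timepoint = 1:5,
#'                      x_um = c(0, 1, 1, 1, 1), y_um = 0, z_um = 0)
#' ema_smooth_tracks(tr, window = 10)$x_um
ema_smooth_tracks <- function(tracks, window = 10L) {
  tracks <- validate_tracks(tracks)
  stopifnot(window >= 1)
  alpha <- 2 / (window + 1)
  tracks <- dplyr::arrange(tracks, .data$track_id, .data$timepoint)
  n_t <- length(unique(tracks$timepoint))
  ema1 <- function(x) {
    as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                             init = x[1L]))
  }
  dplyr::mutate(dplyr::group_by(tracks, .data$track_id),
                dplyr::across(c("x_um", "y_um", "z_um"), ema1)) |>
    dplyr::ungroup()
}

validate_tracks <- function(tracks) {
  tracks <- tibble::as_tibble(tracks)
  need <- c("track_id", "timepoint", "x_um", "y_um", "z_um")
  if (!all(need %in% names(tracks))) {
    rlang::abort(paste("track table must have columns",
                       paste(need, collapse = ", ")),
                 class = "morphoring_format_error")
  }
  if (anyDuplicated(tracks[, c("track_id", "timepoint")])) {
    rlang::abort("duplicate (track_id, timepoint) rows",
                 class = "morphoring_format_error")
  }
  if (!all(is.finite(as.matrix(tracks[, c("x_um", "y_um", "z_um")])))) {
    rlang::abort("non-finite positions", class = "morphoring_format_error")
  }
  tps <- sort(unique(tracks$timepoint))
  counts <- table(tracks$track_id)
  if (length(unique(counts)) != 1L || counts[1L] != length(tps)) {
    bad <- names(counts)[counts != length(tps)]
    rlang::abort(sprintf(
      "%d track(s) do not span every timepoint (e.g. %s)", length(bad),
      bad[1L]), class = "morphoring_incomplete_track")
  }
  if (length(unique(tracks$track_id)) < 3L) {
    rlang::abort("need at least 3 tracks", class = "morphoring_format_error")
  }
  tracks
}

#' Map first-frame positions to cylindrical band coordinates
#'
#' Projects the centered positions into the eigenspace of their covariance
#' matrix and keeps the axial coordinate `w` (projection on the band's
#' cylinder axis) and the azimuth `phi` in the orthogonal plane.  For a
#' ring-shaped band the cylinder axis is the smallest-variance eigenvector
#' (the two in-plane directions carry the ring's spread); a correlation
#' matrix would be near-isotropic on such data and leave the eigenbasis
#' undefined.  The sign of `w` is fixed data-intrinsically: the low-`w` end
#' is the one with the smaller mean cylindrical radius (the inner rows of
#' the band enclose less), so the mapping is invariant under rigid motions
#' of the input.
#'
#' @param first_frame A data frame or matrix of first-timepoint positions
#'   (columns `x_um`, `y_um`, `z_um`, optionally `track_id`).
#' @return A tibble with `track_id`, `w`, `phi`, with the eigenbasis and
#'   centering stored in attributes.
#' @export
map_to_cylindrical <- function(first_frame) {
  if (is.matrix(first_frame)) {
    P <- first_frame
    id <- seq_len(nrow(P))
  } else {
    ff <- tibble::as_tibble(first_frame)
    id <- if ("track_id" %in% names(ff)) ff$track_id else seq_len(nrow(ff))
    P <- as.matrix(ff[, intersect(c("x_um", "y_um", "z_um"), names(ff))])
    if (ncol(P) != 3L) P <- as.matrix(ff[, 1:3])
  }
  if (nrow(P) < 3L) {
    rlang::abort("need at least 3 positions",
                 class = "morphoring_degenerate_configuration")
  }
  ctr <- colMeans(P)
  Z <- sweep(P, 2L, ctr)
  ev <- eigen(stats::cov(Z), symmetric = TRUE)
  if (ev$values[2L] < 1e-12 * ev$values[1L]) {
    rlang::abort("degenerate configuration: positions are collinear",
                 class = "morphoring_degenerate_configuration")
  }
  # axis = smallest-variance eigenvector; azimuth plane = the two largest
  S <- Z %*% ev$vectors[, c(3L, 1L, 2L)]
  w <- S[, 1L]
  rho <- sqrt(S[, 2L]^2 + S[, 3L]^2)
  # inner (small cylindrical radius) end gets small w
  lo <- w <= stats::quantile(w, 0.2)
  hi <- w >= stats::quantile(w, 0.8)
  if (mean(rho[lo]) > mean(rho[hi])) {
    w <- -w
    S[, 2L] <- -S[, 2L]          # keep the frame right-handed
  }
  phi <- atan2(S[, 3L], S[, 2L])
  out <- tibble::tibble(track_id = id, w = w, phi = phi)
  attr(out, "center") <- ctr
  attr(out, "basis") <- ev$vectors
  out
}

#' Assign nuclei to contour bins by axial coordinate
#'
#' Bins the axial coordinate `w` of the first-frame cylindrical map into
#' `n_bins` bands; bin 1 is the innermost (smallest `w`).  Labels are
#' assigned once, at the first timepoint, and propagated forward unchanged.
#'
#' @param cyl Result of [map_to_cylindrical()].
#' @param n_bins Number of bins (default 5).
#' @param method `"width"` for equal-width bins over the occupied range
#'   (default) or `"count"` for equal-count bins.
#' @return An integer vector of bin labels (1 to `n_bins`) named by
#'   `track_id`.  A bin with fewer than 8 members raises a warning
#'   (`morphoring_empty_bin`); fewer than 4 is an error.
#' @export
assign_bins <- function(cyl, n_bins = 5L, method = c("width", "count")) {
  method <- match.arg(method)
  w <- cyl$w
  if (diff(range(w)) < 1e-12) {
    rlang::abort("all axial coordinates equal: cannot bin",
                 class = "morphoring_empty_bin")
  }
  if (method == "width") {
    br <- seq(min(w), max(w), length.out = n_bins + 1L)
    br[1L] <- br[1L] - 1e-9; br[n_bins + 1L] <- br[n_bins + 1L] + 1e-9
    bins <- as.integer(cut(w, br))
  } else {
    bins <- as.integer(cut(rank(w, ties.method = "first"),
                           seq(0, length(w), length.out = n_bins + 1L)))
  }
  counts <- tabulate(bins, n_bins)
  if (any(counts < 4L)) {
    rlang::abort(sprintf("bin %d has only %d members",
                         which.min(counts), min(counts)),
                 class = "morphoring_empty_bin")
  }
  if (any(counts < 8L)) {
    rlang::warn(sprintf("bin %d has only %d members: contour fit may be poor",
                        which.min(counts), min(counts)),
                class = "morphoring_empty_bin_warning")
  }
  stats::setNames(bins, cyl$track_id)
}

#' Fit a closed contour through one bin of nuclei
#'
#' Points are sorted by their initial azimuth, repeated three times to
#' suppress edge effects, smoothed per dimension with a cubic smoothing
#' spline (csaps parameterization, penalty `smoothing`, index sites), and
#' the loop is closed by walking simultaneously forward and backward from
#' the midpoint of the repeated array until the two knots fall within a
#' fixed tolerance (`closure_factor` times the median inter-knot spacing).
#' The closed curve is then resampled to `n_out` points at constant
#' arclength.
#'
#' @param points_3d Matrix or data frame of the bin's positions (n x 3).
#' @param order_angles Initial azimuths used for ordering (length n).
#' @param smoothing csaps penalty parameter in `(0, 1]` (default 0.01).
#' @param n_out Number of output points (default 500).
#' @param closure_factor Loop-closure tolerance as a multiple of the median
#'   inter-knot spacing.
#' @return A tibble of class `ring_contour` with columns `point_index`,
#'   `s` (arclength, microns), `x`, `y`, `z`; total length in
#'   `attr(, "length")`.
#' @export
fit_closed_contour <- function(points_3d, order_angles, smoothing = 0.01,
                               n_out = 500L, closure_factor = 0.5) {
  P <- as.matrix(points_3d)
  m <- nrow(P)
  if (m < 4L) {
    rlang::abort("need at least 4 points to fit a contour",
                 class = "morphoring_too_few_points")
  }
  stopifnot(length(order_angles) == m)
  ev <- eigen(stats::cov(P), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] < 1e-10 * ev[1L]) {
    rlang::abort("points are collinear: no closed loop exists",
                 class = "morphoring_loop_closure_failure")
  }
  ord <- order(order_angles)
  P <- P[ord, , drop = FALSE]
  P3 <- rbind(P, P, P)
  sites <- seq_len(3L * m)
  fits <- lapply(1:3, function(k) csaps_fit(sites, P3[, k], smoothing))
  sm <- vapply(fits, function(f) f(sites), numeric(3L * m))
  mid <- ceiling(3L * m / 2)
  spacing <- sqrt(rowSums((sm[-1L, , drop = FALSE] -
                             sm[-nrow(sm), , drop = FALSE])^2))
  tol <- closure_factor * stats::median(spacing)
  j_lo <- max(1L, floor(0.35 * m)); j_hi <- min(ceiling(0.65 * m), mid - 2L)
  period <- NA_integer_; j_close <- NA_integer_
  for (j in j_lo:j_hi) {
    if (mid + j > 3L * m) break
    # the matched pair sits 2j (even loop) or 2j + 1 (odd loop) knots apart
    d_even <- sqrt(sum((sm[mid + j, ] - sm[mid - j, ])^2))
    d_odd <- sqrt(sum((sm[mid + j, ] - sm[mid - j - 1L, ])^2))
    if (d_even < tol) { j_close <- j; period <- 2L * j; break }
    if (d_odd < tol) { j_close <- j; period <- 2L * j + 1L; break }
  }
  if (is.na(j_close)) {
    rlang::abort("loop closure failed: no knot pair within tolerance",
                 class = "morphoring_loop_closure_failure")
  }
  idx <- (mid + j_close - period):(mid + j_close - 1L)  # one full period
  # dense evaluation of the fitted splines over the kept interval
  sq <- seq(mid + j_close - period, mid + j_close,
            length.out = 40L * length(idx))
  D <- cbind(fits[[1L]](sq), fits[[2L]](sq), fits[[3L]](sq))
  seg <- sqrt(rowSums((D[-1L, ] - D[-nrow(D), ])^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  s_out <- seq(0, L, length.out = n_out + 1L)[-(n_out + 1L)]
  out <- vapply(1:3, function(k) stats::approx(arc, D[, k], xout = s_out)$y,
                numeric(n_out))
  res <- tibble::tibble(point_index = seq_len(n_out), s = s_out,
                        x = out[, 1L], y = out[, 2L], z = out[, 3L])
  attr(res, "length") <- L
  class(res) <- c("ring_contour", class(res))
  res
}

#' Length, area and roundness of a contour
#'
#' `L` is the contour length (arclength of the fitted curve), `A` the
#' bilateral-midline Riemann area: the contour is split at its two extreme
#' points along `axis` (the dorsoventral direction; by default the
#' contour's own first principal axis, which makes the metric invariant
#' under rigid motions), the two arms are paired at equal normalized arc
#' position, and rung length times midline step is summed.  `R = A / L^2`.
#'
#' @param contour A `ring_contour` (or any n x 3 point matrix of an ordered
#'   closed curve).
#' @param axis Optional 3-vector giving the split direction.
#' @return Named numeric vector `c(L = , A = , R = )`.
#' @export
contour_metrics <- function(contour, axis = NULL) {
  P <- contour_points(contour)
  L <- if (!is.null(attr(contour, "length"))) attr(contour, "length")
       else polyline_length_closed(P)
  if (is.null(axis)) {
    pc <- eigen(stats::cov(P), symmetric = TRUE)$vectors[, 1L]
    axis <- pc * sign(pc[which.max(abs(pc))])
  }
  proj <- as.numeric(P %*% (axis / sqrt(sum(axis^2))))
  if (diff(range(proj)) < 1e-9 * (1 + max(abs(P)))) {
    rlang::abort("degenerate contour: extreme points coincide",
                 class = "morphoring_degenerate_contour")
  }
  i_top <- which.max(proj); i_bot <- which.min(proj)
  if (i_top == i_bot) {
    rlang::abort("degenerate contour: extreme points coincide",
                 class = "morphoring_degenerate_contour")
  }
  A <- midline_area_split(P, i_top, i_bot)
  c(L = L, A = A, R = A / L^2)
}

contour_points <- function(contour) {
  if (is.matrix(contour)) return(contour)
  as.matrix(tibble::as_tibble(contour)[, c("x", "y", "z")])
}

polyline_length_closed <- function(P) {
  sum(sqrt(rowSums((P[c(2:nrow(P), 1L), ] - P)^2)))
}

reindex_from <- function(P, i) {
  if (i == 1L) P else P[c(i:nrow(P), 1:(i - 1L)), , drop = FALSE]
}

#' Minor and major axis lengths of a contour
#'
#' Extents of the contour along the anteroposterior and left-right
#' directions of the embryo frame: `f_y` is the AP (major) extent and
#' `f_x` the left-right (minor) extent.
#'
#' @param contour A `ring_contour` or point matrix.
#' @param ap_axis,lr_axis Unit 3-vectors of the embryo frame (defaults
#'   `x` and `y`).
#' @return Named numeric vector `c(f_x = , f_y = )`.
#' @export
axis_lengths <- function(contour, ap_axis = c(1, 0, 0),
                         lr_axis = c(0, 1, 0)) {
  P <- contour_points(contour)
  pr_ap <- as.numeric(P %*% (ap_axis / sqrt(sum(ap_axis^2))))
  pr_lr <- as.numeric(P %*% (lr_axis / sqrt(sum(lr_axis^2))))
  c(f_x = diff(range(pr_lr)), f_y = diff(range(pr_ap)))
}

#' In-plane principal extents of a contour
#'
#' Extents of the contour along the two principal directions of its own
#' best-fit plane: `f_y` is the major (larger) and `f_x` the minor extent.
#' For contours that wrap around the embryo pole these are the natural
#' ellipse axes driving the coupled-ring model, whereas the embryo-frame
#' projections of [axis_lengths()] degenerate.
#'
#' @param contour A `ring_contour` or point matrix.
#' @return Named numeric vector `c(f_x = , f_y = )`.
#' @export
contour_plane_axes <- function(contour) {
  P <- contour_points(contour)
  ev <- eigen(stats::cov(P), symmetric = TRUE)$vectors
  e1 <- as.numeric(P %*% ev[, 1L]); e2 <- as.numeric(P %*% ev[, 2L])
  ext <- sort(c(diff(range(e1)), diff(range(e2))))
  c(f_x = ext[1L], f_y = ext[2L])
}

#' Mean distances from the middle contour to its neighbors
#'
#' For each of the middle contour's points, the distance to the nearest
#' point of the inner (resp. outer) contour is found; `d_i` and `d_o` are
#' the means of these distances.
#'
#' @param inner,middle,outer Contours at the same timepoint.
#' @return Named numeric vector `c(d_i = , d_o = )`.
#' @export
intercontour_distances <- function(inner, middle, outer) {
  M <- contour_points(middle)
  nearest_mean <- function(Q) {
    # pairwise distances in blocks to keep memory modest
    d2 <- outer(rowSums(M^2), rowSums(Q^2), "+") - 2 * M %*% t(Q)
    mean(sqrt(pmax(apply(d2, 1L, min), 0)))
  }
  c(d_i = nearest_mean(contour_points(inner)),
    d_o = nearest_mean(contour_points(outer)))
}

#' Normalize metrics to a reference position and add the arclength position
#'
#' Each metric series is divided by its value at the timepoint when the
#' contour's ventral-most point first reaches the reference sagittal angle
#' (default: the initial angle of the innermost contour).  The position
#' coordinate `s_pos` is the incomplete elliptic arclength
#' `E(theta, eps)` along the sagittal section of the embryo ellipsoid.
#'
#' @param metrics A metrics tibble with columns `bin`, `timepoint`,
#'   `theta_ventral` and the metric columns `L`, `A`, `R`.
#' @param eccentricity Eccentricity of the sagittal ellipse (default 0.92).
#' @param theta_ref Reference angle; default the `theta_ventral` of the
#'   innermost bin at the first timepoint.
#' @return The metrics tibble with added `s_pos`, `L_norm`, `A_norm`,
#'   `R_norm` columns.  Contours that never reach the reference angle fall
#'   back to their first timepoint with a `morphoring_reference_not_crossed`
#'   warning.
#' @export
normalize_and_reparameterize <- function(metrics, eccentricity = 0.92,
                                         theta_ref = NULL) {
  stopifnot(all(c("bin", "timepoint", "theta_ventral", "L", "A", "R") %in%
                  names(metrics)))
  if (is.null(theta_ref)) {
    first_inner <- metrics[metrics$bin == min(metrics$bin), ]
    theta_ref <- first_inner$theta_ventral[which.min(first_inner$timepoint)]
  }
  metrics$s_pos <- elliptic_arc(metrics$theta_ventral, eccentricity)
  norm_one <- function(df) {
    df <- df[order(df$timepoint), ]
    hit <- which(df$theta_ventral >= theta_ref - 1e-12)
    if (length(hit) == 0L) {
      rlang::warn(sprintf(
        "bin %d never reaches the reference angle; normalizing by its first timepoint",
        df$bin[1L]), class = "morphoring_reference_not_crossed")
      ref <- 1L
    } else {
      ref <- hit[1L]
    }
    df$L_norm <- df$L / df$L[ref]
    df$A_norm <- df$A / df$A[ref]
    df$R_norm <- df$R / df$R[ref]
    df
  }
  dplyr::bind_rows(lapply(split(metrics, metrics$bin), norm_one))
}

#' Run the full contour-kinematics pipeline
#'
#' Smooths the tracks, maps the first frame to cylindrical coordinates,
#' assigns fixed bins, fits a closed contour per bin and timepoint, and
#' computes the shape-metric time series (length, midline area, roundness,
#' axis extents, intercontour distances, normalized series and sagittal
#' position).
#'
#' @param tracks Long-format track table (`track_id`, `timepoint`, `x_um`,
#'   `y_um`, `z_um`).
#' @param n_bins,window,smoothing,n_out Pipeline parameters (defaults 5,
#'   10, 0.01, 500).
#' @param bin_method Passed to [assign_bins()].
#' @param ap_axis,lr_axis,dv_axis Embryo-frame directions used for the axis
#'   extents and the ventral-most point (defaults: AP = `x`, LR = `y`,
#'   dorsal = `+z`).
#' @param eccentricity Sagittal eccentricity for [
#'   normalize_and_reparameterize()].
#' @param embryo_center Center of the embryo for sagittal angles (default
#'   origin).
#' @return A list of class `kinematics_result` with `contours` (tibble:
#'   `bin`, `timepoint`, `point_index`, `s`, `x`, `y`, `z`), `metrics`
#'   (tibble per bin and timepoint), `bins`, `map`, and the parameters.
#' @export
#' @examples
#' \donttest{
#' sim <- generate_tracks(generator_params(n_nuclei = 150, n_timepoints = 12,
#'                                         noise_sigma = 0, n_rows = 3))
#' res <- run_kinematics(sim$tracks, n_bins = 3)
#' head(res$metrics)
#' }
run_kinematics <- function(tracks, n_bins = 5L, window = 10L,
                           smoothing = 0.01, n_out = 500L,
                           bin_method = "width",
                           ap_axis = c(1, 0, 0), lr_axis = c(0, 1, 0),
                           dv_axis = c(0, 0, 1), eccentricity = 0.92,
                           embryo_center = c(0, 0, 0)) {
  sm <- ema_smooth_tracks(tracks, window = window)
  tps <- sort(unique(sm$timepoint))
  first <- sm[sm$timepoint == tps[1L], ]
  cyl <- map_to_cylindrical(first)
  bins <- assign_bins(cyl, n_bins = n_bins, method = bin_method)
  phi_of <- stats::setNames(cyl$phi, cyl$track_id)

  contours <- vector("list", n_bins * length(tps))
  metrics <- vector("list", n_bins * length(tps))
  k <- 0L
  for (tp in tps) {
    frame <- sm[sm$timepoint == tp, ]
    frame <- frame[order(frame$track_id), ]
    for (b in seq_len(n_bins)) {
      ids <- names(bins)[bins == b]
      sub <- frame[as.character(frame$track_id) %in% ids, ]
      ct <- fit_closed_contour(as.matrix(sub[, c("x_um", "y_um", "z_um")]),
                               phi_of[as.character(sub$track_id)],
                               smoothing = smoothing, n_out = n_out)
      cm <- contour_metrics(ct)
      ax <- axis_lengths(ct, ap_axis = ap_axis, lr_axis = lr_axis)
      axp <- contour_plane_axes(ct)
      P <- contour_points(ct)
      rel <- sweep(P, 2L, embryo_center)
      dvp <- as.numeric(rel %*% (dv_axis / sqrt(sum(dv_axis^2))))
      iv <- which.min(dvp)
      apx <- as.numeric(rel[iv, ] %*% (ap_axis / sqrt(sum(ap_axis^2))))
      th <- sign(dvp[iv] + 1e-300) *
        acos(pmax(-1, pmin(1, apx / sqrt(sum(rel[iv, ]^2)))))
      k <- k + 1L
      contours[[k]] <- dplyr::mutate(tibble::as_tibble(ct), bin = b,
                                     timepoint = tp, .before = 1L)
      metrics[[k]] <- tibble::tibble(
        bin = b, timepoint = tp, L = cm["L"], A = cm["A"], R = cm["R"],
        f_x = ax["f_x"], f_y = ax["f_y"],
        f_x_plane = axp["f_x"], f_y_plane = axp["f_y"],
        theta_ventral = th)
    }
  }
  contours <- dplyr::bind_rows(contours)
  metrics <- dplyr::bind_rows(metrics)
  # intercontour distances: middle bin vs innermost and outermost
  b_mid <- (n_bins + 1L) %/% 2L
  dd <- lapply(tps, function(tp) {
    gi <- function(b) {
      cc <- contours[contours$bin == b & contours$timepoint == tp, ]
      as.matrix(cc[, c("x", "y", "z")])
    }
    di <- intercontour_distances(gi(1L), gi(b_mid), gi(n_bins))
    tibble::tibble(bin = b_mid, timepoint = tp, d_i = di["d_i"],
                   d_o = di["d_o"])
  })
  metrics <- dplyr::left_join(metrics, dplyr::bind_rows(dd),
                              by = c("bin", "timepoint"))
  metrics <- normalize_and_reparameterize(metrics,
                                          eccentricity = eccentricity)
  structure(list(contours = contours,
                 metrics = dplyr::arrange(metrics, .data$bin,
                                          .data$timepoint),
                 bins = bins, map = cyl,
                 params = list(n_bins = n_bins, window = window,
                               smoothing = smoothing, n_out = n_out,
                               ap_axis = ap_axis, lr_axis = lr_axis,
                               dv_axis = dv_axis,
                               eccentricity = eccentricity)),
            class = "kinematics_result")
}

#' @export
print.kinematics_result <- function(x, ...) {
  cat(sprintf(
    "<kinematics_result> %d bins x %d timepoints; %d contour points each\n",
    x$params$n_bins, length(unique(x$metrics$timepoint)), x$params$n_out))
  invisible(x)
}

#' Two-piece linear changepoint of a metric series
#'
#' Advisory detector of the S1 to S2 transition: fits two straight lines
#' with a common breakpoint to a metric series (by default the middle
#' contour's roundness) and returns the breakpoint minimizing the residual
#' sum of squares.
#'
#' @param timepoint,value Numeric vectors of equal length.
#' @return A list with `changepoint` and `rss`.
#' @export
detect_stage_change <- function(timepoint, value) {
  stopifnot(length(timepoint) == length(value), length(value) >= 6L)
  o <- order(timepoint)
  tt <- timepoint[o]; vv <- value[o]
  n <- length(tt)
  best <- list(changepoint = NA_real_, rss = Inf)
  for (k in 3L:(n - 3L)) {
    r1 <- sum(stats::lm.fit(cbind(1, tt[1:k]), vv[1:k])$residuals^2)
    r2 <- sum(stats::lm.fit(cbind(1, tt[(k + 1L):n]),
                            vv[(k + 1L):n])$residuals^2)
    if (r1 + r2 < best$rss) best <- list(changepoint = tt[k], rss = r1 + r2)
  }
  best
}
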