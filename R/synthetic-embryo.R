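# Synthetic embryo track generator: a ring band of nuclei near the posterior
# pole of a 2.5:1:1 ellipsoid, advected by a two-stage flow (S1: dorsal
# translation with mild band widening; S2: per-row area contraction), with
# additive positional noise and exact per-row ground truth.

#' Parameters of the synthetic track generator
#'
#' Defaults emulate the study conditions: about 475 nuclei in a 5-row band
#' near the posterior pole of a 115.6 x 46.25 x 46.25 micron ellipsoid,
#' followed over 100 timepoints.  Stage S1 (the first `s1_fraction` of the
#' movie) translates the band toward dorsal along the sagittal plane while
#' the band widens slightly (middle row unchanged, inner rows tightening,
#' outer rows spreading -- the in-plane AP stretch seen between contours in
#' live data); stage S2 contracts each row's enclosed area linearly to
#' `contraction_final` times its initial value, inner rows leading outer
#' rows by `s2_lag` timepoints.  Isotropic Gaussian noise of `noise_sigma`
#' microns is added to every recorded position.
#'
#' @param semi_axes Embryo ellipsoid semi-axes in microns.
#' @param n_nuclei Total nuclei (distributed evenly over rows).
#' @param n_rows Number of band rows (contours).
#' @param n_timepoints Number of timepoints.
#' @param s1_fraction Fraction of timepoints in stage S1.
#' @param u_band Angular radius of the middle row about the band center
#'   (radians on the direction sphere).
#' @param row_spacing Angular spacing between adjacent rows.
#' @param translation_speed Dorsal translation speed in microns per
#'   timepoint (arc length along the sagittal section at the band).
#' @param band_widening Fractional change of the outermost row radius over
#'   S1 (the innermost row changes by the opposite sign).
#' @param contraction_final Final enclosed-area multiplier of each row
#'   relative to its initial area.
#' @param s2_lag Timepoints by which each row lags the next-inner row in
#'   starting its contraction.
#' @param noise_sigma Standard deviation of the positional noise (microns).
#' @param seed Integer seed making the track table reproducible.
#' @return A list of class `generator_params`.
#' @export
#' @examples
#' generator_params(n_timepoints = 20)
generator_params <- function(semi_axes = c(115.6, 46.25, 46.25),
                             n_nuclei = 475L, n_rows = 5L,
                             n_timepoints = 100L, s1_fraction = 0.6,
                             u_band = 0.6, row_spacing = 0.04,
                             translation_speed = 0.15,
                             band_widening = 0.18,
                             contraction_final = 0.6,
                             s2_lag = 3L, noise_sigma = 0.5, seed = 0L) {
  p <- list(semi_axes = semi_axes, n_nuclei = as.integer(n_nuclei),
            n_rows = as.integer(n_rows),
            n_timepoints = as.integer(n_timepoints),
            s1_fraction = s1_fraction, u_band = u_band,
            row_spacing = row_spacing,
            translation_speed = translation_speed,
            band_widening = band_widening,
            contraction_final = contraction_final,
            s2_lag = as.integer(s2_lag), noise_sigma = noise_sigma,
            seed = as.integer(seed))
  if (any(!is.finite(unlist(p))) || p$n_nuclei < p$n_rows * 4L ||
      p$n_rows < 1L || p$n_timepoints < 2L || p$s1_fraction <= 0 ||
      p$s1_fraction > 1 || p$u_band <= (p$n_rows %/% 2L) * p$row_spacing ||
      p$noise_sigma < 0 || p$contraction_final <= 0) {
    rlang::abort("inconsistent generator parameters",
                 class = "morphoring_params_error")
  }
  structure(p, class = "generator_params")
}

#' Preset generator parameter sets
#'
#' `"wildtype"` is the full two-stage flow; `"translation-only"` disables
#' the S2 contraction; `"contraction-only"` disables the S1 translation and
#' widening; `"static"` disables everything (constant positions plus
#' noise).
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [generator_params()].
#' @return A `generator_params` object.
#' @export
generator_preset <- function(preset = c("wildtype", "translation-only",
                                        "contraction-only", "static"),
                             ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "wildtype" = list(),
    "translation-only" = list(contraction_final = 1),
    "contraction-only" = list(translation_speed = 0, band_widening = 0),
    "static" = list(translation_speed = 0, band_widening = 0,
                    contraction_final = 1))
  do.call(generator_params, utils::modifyList(args, list(...)))
}

# direction-sphere circle of angular radius rho about the sagittal center
# direction at angle beta from +x toward +z, radially projected onto the
# ellipsoid; azimuth tt = 0 points dorsal (+z side)
band_circle_points <- function(ax, beta, rho, tt) {
  ctr <- c(cos(beta), 0, sin(beta))
  e1 <- c(-sin(beta), 0, cos(beta))
  e2 <- c(0, -1, 0)
  D <- outer(rep(cos(rho), length(tt)), ctr) +
    sin(rho) * (outer(cos(tt), e1) + outer(sin(tt), e2))
  lam <- 1 / sqrt((D[, 1L] / ax[1L])^2 + (D[, 2L] / ax[2L])^2 +
                    (D[, 3L] / ax[3L])^2)
  D * lam
}

# per-row kinematic schedule: center angle beta(t), radius rho(t), and the
# S2 homothety factor relative to the end-of-S1 curve
row_schedule <- function(params, row) {
  p <- params
  t_all <- seq_len(p$n_timepoints)
  t_s1 <- max(2L, round(p$s1_fraction * p$n_timepoints))
  # meridian scale (microns per radian) at the band, for speed conversion
  scale_m <- sqrt(p$semi_axes[1L]^2 * sin(p$u_band)^2 +
                    p$semi_axes[2L]^2 * cos(p$u_band)^2)
  beta_rate <- p$translation_speed / scale_m
  s1_prog <- pmin(t_all - 1L, t_s1 - 1L) / (t_s1 - 1L)
  beta <- beta_rate * (t_s1 - 1L) * s1_prog
  mid <- (p$n_rows + 1L) / 2
  w_row <- p$band_widening * (row - mid) / max(1, (p$n_rows - 1L) / 2)
  rho0 <- p$u_band + (row - mid) * p$row_spacing
  rho <- rho0 * (1 + w_row * s1_prog)
  # S2: all rows contract along the same linear ramp, each shifted by
  # (row - 1) * s2_lag so inner rows lead outer rows throughout; rows that
  # finish early hold their final area
  t_start <- min(t_s1 + (row - 1L) * p$s2_lag, p$n_timepoints - 1L)
  ramp <- max(1L, p$n_timepoints - t_s1 - (p$n_rows - 1L) * p$s2_lag)
  g <- rep(1, p$n_timepoints)
  if (p$contraction_final != 1) {
    prog <- pmin(pmax((t_all - t_start) / ramp, 0), 1)
    g <- 1 + (p$contraction_final - 1) * prog
  }
  list(beta = beta, rho = rho, g = g, t_s1 = t_s1)
}

#' Generate synthetic nuclear tracks with ground truth
#'
#' Builds the two-stage synthetic embryo (see [generator_params()]) and
#' returns the long-format track table together with exact per-row metrics.
#' Within each row the nuclei sit at fixed material azimuths of the row
#' curve, so the noisy tracks sample a known deforming contour; the ground
#' truth is computed from densely sampled noise-free row curves.
#'
#' @param params A [generator_params()] object.
#' @return A list with `tracks` (tibble: `track_id`, `timepoint`, `x_um`,
#'   `y_um`, `z_um`), `truth` (tibble: `row`, `timepoint`, `L`, `A`, `R`,
#'   `theta_ventral`), `row_of_track` (integer vector mapping track id to
#'   row), and `params`.
#' @export
#' @examples
#' sim <- generate_tracks(generator_params(n_nuclei = 60, n_timepoints = 10,
#'                                         noise_sigma = 0))
#' dplyr::count(sim$tracks, timepoint)[1:3, ]
generate_tracks <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  ax <- p$semi_axes
  if (!is.null(p$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(p$seed)
  }
  per_row <- diff(round(seq(0, p$n_nuclei, length.out = p$n_rows + 1L)))
  t_dense <- seq(0, 2 * pi, length.out = 513L)[-513L]
  tracks <- vector("list", p$n_rows)
  truth <- vector("list", p$n_rows)
  row_of_track <- integer(0L)
  id0 <- 0L
  for (r in seq_len(p$n_rows)) {
    sch <- row_schedule(p, r)
    m <- per_row[r]
    t_mat <- 2 * pi * (seq_len(m) - 1L) / m
    # noise-free dense curves per timepoint, for ground truth and the S2
    # centroid/homothety bookkeeping
    pos_r <- array(NA_real_, c(m, 3L, p$n_timepoints))
    tr_rows <- vector("list", p$n_timepoints)
    G <- NULL; base_dense <- NULL; base_pts <- NULL
    A0 <- NA_real_; A_end <- NA_real_
    for (tp in seq_len(p$n_timepoints)) {
      beta <- sch$beta[tp]; rho <- sch$rho[tp]
      dense <- band_circle_points(ax, beta, rho, t_dense)
      pts <- band_circle_points(ax, beta, rho, t_mat)
      if (tp == 1L) A0 <- midline_area_dense(dense)
      if (sch$g[tp] < 1) {
        if (is.null(G)) {
          # freeze the end-of-S1 configuration for this row
          base_dense <- dense; base_pts <- pts
          G <- colMeans(base_dense)
          A_end <- midline_area_dense(base_dense)
        }
        lam <- sqrt(sch$g[tp] * A0 / A_end)
        dense <- sweep(sweep(base_dense, 2L, G) * lam, 2L, G, "+")
        pts <- sweep(sweep(base_pts, 2L, G) * lam, 2L, G, "+")
      }
      pos_r[, , tp] <- pts
      truth[[r]][[tp]] <- row_truth_metrics(dense, r, tp)
    }
    noise <- array(stats::rnorm(m * 3L * p$n_timepoints, 0, p$noise_sigma),
                   c(m, 3L, p$n_timepoints))
    pos_r <- pos_r + noise
    tracks[[r]] <- tibble::tibble(
      track_id = rep(id0 + seq_len(m), times = p$n_timepoints),
      timepoint = rep(seq_len(p$n_timepoints), each = m),
      x_um = as.vector(pos_r[, 1L, ]),
      y_um = as.vector(pos_r[, 2L, ]),
      z_um = as.vector(pos_r[, 3L, ]))
    row_of_track <- c(row_of_track, rep(r, m))
    id0 <- id0 + m
  }
  truth_tb <- dplyr::bind_rows(lapply(truth, dplyr::bind_rows))
  list(tracks = dplyr::arrange(dplyr::bind_rows(tracks), .data$timepoint,
                               .data$track_id),
       truth = truth_tb,
       row_of_track = row_of_track,
       params = p)
}

# ground-truth metrics of one dense noise-free row curve
row_truth_metrics <- function(dense, row, tp) {
  m <- nrow(dense)
  L <- sum(sqrt(rowSums((dense[c(2:m, 1L), ] - dense)^2)))
  A <- midline_area_dense(dense)
  iv <- which.min(dense[, 3L])
  # sagittal direction angle of the ventral-most point, signed toward +z
  th <- sign(dense[iv, 3L] + 1e-300) * dir_colatitude(dense[iv, ])
  tibble::tibble(row = row, timepoint = tp, L = L, A = A, R = A / L^2,
                 theta_ventral = th)
}

dir_colatitude <- function(pt) {
  acos(pmax(-1, pmin(1, pt[1L] / sqrt(sum(pt^2)))))
}

# bilateral-midline Riemann area of a closed 3D polyline: the curve is
# split at its two extreme points along the split direction, the two arms
# are paired at equal normalized arc positions, and rung length times
# midline step is summed.  The generator's ground truth splits along the
# dorsoventral (z) axis.
midline_area_dense <- function(P) {
  midline_area_split(P, which.max(P[, 3L]), which.min(P[, 3L]))
}

midline_area_split <- function(P, i_top, i_bot) {
  m <- nrow(P)
  if (i_top == i_bot) return(0)
  idx1 <- cyclic_span(i_top, i_bot, m)
  idx2 <- rev(cyclic_span(i_bot, i_top, m))
  arm1 <- P[idx1, , drop = FALSE]
  arm2 <- P[idx2, , drop = FALSE]
  s1 <- arc_pos(arm1); s2 <- arc_pos(arm2)
  ns <- 512L
  sq <- seq(0, 1, length.out = ns)
  a1 <- apply(arm1, 2L, function(cc) stats::approx(s1, cc, xout = sq)$y)
  a2 <- apply(arm2, 2L, function(cc) stats::approx(s2, cc, xout = sq)$y)
  rung <- sqrt(rowSums((a1 - a2)^2))
  midp <- (a1 + a2) / 2
  step <- sqrt(rowSums(diff(midp)^2))
  sum((rung[-1L] + rung[-ns]) / 2 * step)
}

cyclic_span <- function(from, to, m) {
  if (from <= to) from:to else c(from:m, 1:to)
}

arc_pos <- function(P) {
  d <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  if (d[length(d)] == 0) return(seq(0, 1, length.out = nrow(P)))
  d / d[length(d)]
}

#' Ground-truth metrics of a generated row
#'
#' @param sim Result of [generate_tracks()].
#' @param row Row index (1 = innermost).
#' @param timepoint Timepoint index.
#' @return A one-row tibble with `L`, `A`, `R`, `theta_ventral`.
#' @export
ground_truth_metrics <- function(sim, row, timepoint) {
  tr <- sim$truth
  out <- tr[tr$row == row & tr$timepoint == timepoint, ]
  if (nrow(out) != 1L) {
    rlang::abort("invalid row/timepoint index", class = "morphoring_index_error")
  }
  out
}
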