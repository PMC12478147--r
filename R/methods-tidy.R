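# broom-style tidiers for the package's fitted/solved objects.

#' Tidy a planar ring solution
#'
#' @param x An `elastica_ring`.
#' @param ... Unused.
#' @return The half-ring profile as a tibble: `s`, `kappa`, `theta`, `x`,
#'   `y`, `area_cum`.
#' @export
tidy.elastica_ring <- function(x, ...) x$profile

#' One-row summary of a planar ring solution
#'
#' @param x An `elastica_ring`.
#' @param ... Unused.
#' @return A tibble with `branch`, `d`, `A`, `lambda0`, `p`, `energy`,
#'   `bc_residual`, `area_residual`, `refined`.
#' @export
glance.elastica_ring <- function(x, ...) {
  tibble::tibble(branch = x$branch, d = x$d, A = x$A,
                 lambda0 = x$lambda0, p = x$p, energy = x$energy,
                 bc_residual = unname(x$residuals["bc"]),
                 area_residual = unname(x$residuals["area"]),
                 refined = x$refined)
}

#' Summarize an enumerated branch set
#'
#' @param x An `elastica_branches` list.
#' @param ... Unused.
#' @return A tibble with one row per branch member: `branch`, `energy`,
#'   `kappa0`, `kappa1`, `ap_symmetric`.
#' @export
tidy.elastica_branches <- function(x, ...) {
  dplyr::bind_rows(lapply(x, function(m) {
    k <- m$profile$kappa
    tibble::tibble(branch = m$branch, energy = m$energy,
                   kappa0 = k[1L], kappa1 = k[length(k)],
                   ap_symmetric = is_ap_symmetric(m))
  }))
}

#' Tidy a surface ring
#'
#' @param x A `surface_ring`.
#' @param ... Unused.
#' @return The sampled curve as a tibble (`t`, `u`, `v`, `x`, `y`, `z`,
#'   `kappa_g`, `kappa_n`).
#' @export
tidy.surface_ring <- function(x, ...) x$samples

#' One-row summary of a surface ring
#'
#' @param x A `surface_ring`.
#' @param ... Unused.
#' @return A tibble with the surface kind, constraint values, energy and
#'   orientation statistic.
#' @export
glance.surface_ring <- function(x, ...) {
  os <- orientation_statistic(x)
  tibble::tibble(surface = x$spec$kind,
                 length = x$length, area_enclosed = x$area_enclosed,
                 energy = x$energy, energy_kind = x$energy_kind,
                 orientation = as.numeric(os),
                 orientation_magnitude = attr(os, "magnitude"),
                 shape_class = if (!is.null(x$shape_class)) x$shape_class
                               else NA_character_)
}

#' Tidy a kinematics result
#'
#' @param x A `kinematics_result`.
#' @param ... Unused.
#' @return The per-bin, per-timepoint metrics tibble.
#' @export
tidy.kinematics_result <- function(x, ...) x$metrics

#' One-row summary of a kinematics run
#'
#' @param x A `kinematics_result`.
#' @param ... Unused.
#' @return A tibble with the run dimensions and parameters.
#' @export
glance.kinematics_result <- function(x, ...) {
  tibble::tibble(n_bins = x$params$n_bins,
                 n_timepoints = length(unique(x$metrics$timepoint)),
                 n_tracks = length(x$bins),
                 window = x$params$window,
                 smoothing = x$params$smoothing,
                 n_out = x$params$n_out)
}
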