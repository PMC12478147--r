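# ggplot2 display methods.

#' Plot a planar ring solution
#'
#' Draws the full closed ring (upper half-profile plus its lower pairing)
#' in the plane, with the marked points at `(0, 0)` and `(d, 0)`.
#'
#' @param object An `elastica_ring`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elastica_ring <- function(object, ...) {
  fr <- full_ring_curve(object)
  marked <- tibble::tibble(x = c(0, object$d), y = c(0, 0))
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::geom_point(data = marked, size = 2, shape = 21,
                        fill = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s ring, E = %.4f", object$branch, object$energy),
      x = "x (AP)", y = "y") +
    ggplot2::theme_minimal()
}

#' Plot an enumerated branch set
#'
#' Small multiples of the full-ring shapes, one panel per branch member,
#' ordered by energy.
#'
#' @param object An `elastica_branches`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elastica_branches <- function(object, ...) {
  dfs <- lapply(seq_along(object), function(i) {
    m <- object[[i]]
    dplyr::mutate(full_ring_curve(m),
                  panel = sprintf("%02d %s\nE = %.4f", i, m$branch,
                                  m$energy))
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "x (AP)", y = "y") +
    ggplot2::theme_minimal()
}

#' Plot a (d, A) phase diagram
#'
#' Tile plot of the lowest-energy symmetry class over the scanned grid;
#' hatched cells (class `inaccessible`) are geometrically excluded for
#' inextensible deformations.
#'
#' @param object A `ring_phase_diagram` tibble from [scan_phase_diagram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ring_phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$d_rel, y = .data$A_rel,
                               fill = .data$lowest_class)) +
    ggplot2::geom_tile(color = "grey85", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(
      asymmetric = "#b2182b", symmetric = "#2166ac", circle = "#f7f7f7",
      inaccessible = "grey60", unresolved = "grey90")) +
    ggplot2::labs(x = "d / d0", y = "A / A0", fill = "lowest class") +
    ggplot2::theme_minimal()
}

#' Plot a surface ring
#'
#' Dorsal (`x`-`y`) and sagittal (`x`-`z`) projections of the sampled
#' curve.
#'
#' @param object A `surface_ring`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surface_ring <- function(object, ...) {
  s <- object$samples
  df <- dplyr::bind_rows(
    tibble::tibble(h = s$x, v = s$y, view = "dorsal (x-y)"),
    tibble::tibble(h = s$x, v = s$z, view = "sagittal (x-z)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~view) +
    ggplot2::labs(x = "AP position", y = "") +
    ggplot2::theme_minimal()
}

#' Plot kinematics metric time series
#'
#' Normalized length, area and roundness per contour against time,
#' colored from the innermost to the outermost contour.
#'
#' @param object A `kinematics_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kinematics_result <- function(object, ...) {
  m <- object$metrics
  df <- dplyr::bind_rows(
    tibble::tibble(bin = m$bin, timepoint = m$timepoint,
                   metric = "L / L_ref", value = m$L_norm),
    tibble::tibble(bin = m$bin, timepoint = m$timepoint,
                   metric = "A / A_ref", value = m$A_norm),
    tibble::tibble(bin = m$bin, timepoint = m$timepoint,
                   metric = "R / R_ref", value = m$R_norm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$value,
                                   color = factor(.data$bin),
                                   group = .data$bin)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_color_viridis_d(option = "cividis", end = 0.9) +
    ggplot2::labs(x = "timepoint", y = NULL, color = "contour\n(1 = inner)") +
    ggplot2::theme_minimal()
}

#' Plot fitted contours at chosen timepoints
#'
#' @param result A `kinematics_result`.
#' @param timepoints Timepoints to show (default: first, middle, last).
#' @param plane Projection plane: a pair of axis names among
#'   `c("x", "y", "z")`.
#' @return A ggplot.
#' @export
plot_contours <- function(result, timepoints = NULL, plane = c("y", "z")) {
  stopifnot(inherits(result, "kinematics_result"))
  cc <- result$contours
  tps <- sort(unique(cc$timepoint))
  if (is.null(timepoints)) {
    timepoints <- unique(tps[c(1L, ceiling(length(tps) / 2), length(tps))])
  }
  df <- cc[cc$timepoint %in% timepoints, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[plane[1L]]],
                                   y = .data[[plane[2L]]],
                                   color = factor(.data$bin),
                                   group = .data$bin)) +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~timepoint, labeller = ggplot2::label_both) +
    ggplot2::scale_color_viridis_d(option = "cividis", end = 0.9) +
    ggplot2::labs(color = "contour") +
    ggplot2::theme_minimal()
}
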