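# Track-table and results I/O with a reproducibility manifest.

#' Read a nuclear track table
#'
#' Reads a CSV of tracked nuclei into the canonical long format
#' (`track_id`, `timepoint`, `x_um`, `y_um`, `z_um`).  Nonstandard column
#' names (e.g. TrackMate or Mastodon exports) are mapped via `column_map`.
#' Tracks that do not span every timepoint are dropped with a message
#' (typically a few percent of nuclei in real data).
#'
#' @param path CSV file with a header row.
#' @param column_map Named character vector mapping canonical names to the
#'   file's column names, e.g.
#'   `c(track_id = "TRACK_ID", timepoint = "POSITION_T", x_um = "POSITION_X",
#'      y_um = "POSITION_Y", z_um = "POSITION_Z")`.
#' @return A validated complete track tibble.
#' @export
read_tracks <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    rlang::abort(paste("no such file:", path), class = "morphoring_io_failure")
  }
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) {
      rlang::abort(paste("cannot parse CSV:", conditionMessage(e)),
                   class = "morphoring_format_error")
    })
  need <- c("track_id", "timepoint", "x_um", "y_um", "z_um")
  if (!is.null(column_map)) {
    missing_src <- setdiff(column_map, names(raw))
    if (length(missing_src)) {
      rlang::abort(paste("mapped columns not in file:",
                         paste(missing_src, collapse = ", ")),
                   class = "morphoring_format_error")
    }
    for (k in names(column_map)) names(raw)[names(raw) == column_map[k]] <- k
  }
  if (!all(need %in% names(raw))) {
    rlang::abort(paste(
      "missing columns:", paste(setdiff(need, names(raw)), collapse = ", "),
      "(is the file headerless, or does it need a column_map?)"),
      class = "morphoring_format_error")
  }
  tb <- tibble::as_tibble(raw[, need])
  if (nrow(tb) == 0L) {
    rlang::abort("empty track table", class = "morphoring_empty_input")
  }
  # drop incomplete tracks
  tps <- sort(unique(tb$timepoint))
  counts <- table(tb$track_id)
  bad <- names(counts)[counts != length(tps)]
  if (length(bad)) {
    message(sprintf("dropping %d incomplete track(s) of %d", length(bad),
                    length(counts)))
    tb <- tb[!(tb$track_id %in% bad), ]
  }
  validate_tracks(tb)
}

#' Write tracks to CSV
#'
#' @param tracks A track tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  tracks <- dplyr::arrange(tibble::as_tibble(tracks), .data$timepoint,
                           .data$track_id)
  utils::write.csv(tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write kinematics results with a run manifest
#'
#' Writes `contours.csv` (`bin`, `timepoint`, `point_index`, `x`, `y`, `z`),
#' `metrics.csv` (one row per bin and timepoint) and `manifest.json` (the
#' parameters used, a content hash, and the package version) into
#' `out_dir`.  Output ordering is deterministic, so identical inputs give
#' byte-identical files.
#'
#' @param result A `kinematics_result` from [run_kinematics()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written.
#' @export
write_results <- function(result, out_dir) {
  stopifnot(inherits(result, "kinematics_result"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(paste("cannot create", out_dir),
                          class = "morphoring_io_failure")
  }
  contours <- dplyr::arrange(result$contours, .data$bin, .data$timepoint,
                             .data$point_index)
  metrics <- dplyr::arrange(result$metrics, .data$bin, .data$timepoint)
  f1 <- file.path(out_dir, "contours.csv")
  f2 <- file.path(out_dir, "metrics.csv")
  f3 <- file.path(out_dir, "manifest.json")
  utils::write.csv(contours[, c("bin", "timepoint", "point_index",
                                "x", "y", "z")],
                   f1, row.names = FALSE, quote = FALSE)
  utils::write.csv(metrics, f2, row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "morphoring",
    version = as.character(utils::packageVersion("morphoring")),
    params = result$params,
    n_tracks = length(result$bins),
    config_hash = rlang::hash(result$params))
  jsonlite::write_json(manifest, f3, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(f1, f2, f3))
}
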