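# CSV / JSON interchange ---------------------------------------------------
#
# Headered CSV with units in column names is the interchange format between
# stages, so every intermediate is inspectable with any tool.

#' Read and write trajectory / localization tables
#'
#' Trajectories: `traj_id, frame, x_um, y_um` (plus optional `roi`, `fov`);
#' localizations: `frame, x_um, y_um, intensity, sigma_um, quality`;
#' ground truth: `id, frame, x_um, y_um, region, true_D, mobile`.
#'
#' @param x Table to write.
#' @param path CSV path.
#' @return `read_*` return a `data.frame`; `write_*` return `path`
#'   invisibly.
#' @export
write_trajectories_csv <- function(x, path) {
  stopifnot(all(c("traj_id", "frame", "x_um", "y_um") %in% names(x)))
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  x <- read.csv(path)
  stopifnot(all(c("traj_id", "frame", "x_um", "y_um") %in% names(x)))
  x[order(x$traj_id, x$frame), ]
}

#' @rdname write_trajectories_csv
#' @export
write_localizations_csv <- function(x, path) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(x)))
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_localizations_csv <- function(path) {
  x <- read.csv(path)
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(x)))
  x[order(x$frame), ]
}

#' Read / write a concentric-ROI definition as JSON
#'
#' JSON with `center_um` (x, y), `core_radius_um`, `ring_factor`,
#' `out_bound_um` — the parametric form of [build_concentric_rois()].
#'
#' @param roi A `plaque_roi` (parametric form).
#' @param path JSON path.
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "plaque_roi"))
  jsonlite::write_json(list(center_um = roi$center,
                            core_radius_um = roi$core_radius,
                            ring_factor = roi$ring_factor,
                            out_bound_um = roi$out_outer_radius),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_concentric_rois(center = j$center_um,
                        core_radius = j$core_radius_um,
                        ring_factor = j$ring_factor %||% ECS_RING_FACTOR,
                        out_bound = j$out_bound_um)
}
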