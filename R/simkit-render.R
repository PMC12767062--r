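# Movie rendering and TIFF I/O ---------------------------------------------
#
# Coordinate convention (shared across the package): pixel centers sit at
# integer indices starting at 0, origin at the top-left pixel, x along
# columns, y along rows; physical positions are x_um = col0 * pixel_size.

#' Movie container
#'
#' @param frames Numeric 3D array `[rows, cols, n_frames]` (photon counts or
#'   arbitrary units).
#' @param pixel_size Pixel size (um/px).
#' @param frame_interval Frame interval (s).
#' @return Object of class `spt_movie`.
#' @export
spt_movie <- function(frames, pixel_size, frame_interval) {
  stopifnot(length(dim(frames)) == 3, pixel_size > 0, frame_interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval), class = "spt_movie")
}

#' @export
print.spt_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<spt_movie> %d x %d px, %d frames, %.0f nm/px, %.1f ms/frame\n",
              d[1], d[2], d[3], x$pixel_size * 1e3,
              x$frame_interval * 1e3))
  invisible(x)
}

# integrated Gaussian PSF rendered on the pixel grid (photons)
render_emitter <- function(img, x_um, y_um, photons, pixel_size, psf_sigma) {
  nr <- nrow(img); nc <- ncol(img)
  s_px <- psf_sigma / pixel_size
  cx <- x_um / pixel_size  # 0-based pixel coordinates
  cy <- y_um / pixel_size
  cols <- 0:(nc - 1); rows <- 0:(nr - 1)
  fx <- pnorm((cols + 0.5 - cx) / s_px) - pnorm((cols - 0.5 - cx) / s_px)
  fy <- pnorm((rows + 0.5 - cy) / s_px) - pnorm((rows - 0.5 - cy) / s_px)
  img + photons * (fy %o% fx)
}

#' Render a movie from ground-truth trajectories
#'
#' Each emitter is drawn as a 2D Gaussian PSF integrated over pixels
#' (`psf_sigma` from the config), a constant background is added, and
#' optionally Poisson shot noise is applied to signal + background,
#' emulating an EMCCD acquisition at constant emission (no blinking or
#' bleaching). Output values above the 16-bit range are clipped with a
#' warning.
#'
#' @param trajectories Trajectory table (`id`, `frame`, `x_um`, `y_um`);
#'   frames are 0-based. Positions must lie inside the field.
#' @param config A [sim_config()] (pixel size, PSF, photon rate, background).
#' @param noise Apply Poisson shot noise (default `TRUE`).
#' @return An [spt_movie()] with metadata embedded.
#' @export
render_movie <- function(trajectories, config, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  ext <- field_extent_um(config)
  if (nrow(trajectories) > 0 &&
      (any(trajectories$x_um < -config$pixel_size / 2) ||
       any(trajectories$y_um < -config$pixel_size / 2) ||
       any(trajectories$x_um > ext[1]) || any(trajectories$y_um > ext[2])))
    stop("trajectories extend outside the camera field", call. = FALSE)
  nr <- config$field_size[1]; nc <- config$field_size[2]
  frames <- array(config$background, dim = c(nr, nc, config$n_frames))
  if (nrow(trajectories) > 0) {
    by_frame <- split(trajectories, trajectories$frame)
    for (fr in names(by_frame)) {
      f <- as.integer(fr) + 1L
      if (f < 1 || f > config$n_frames) next
      sub <- by_frame[[fr]]
      img <- frames[, , f]
      for (k in seq_len(nrow(sub)))
        img <- render_emitter(img, sub$x_um[k], sub$y_um[k],
                              config$photon_rate, config$pixel_size,
                              config$psf_sigma)
      frames[, , f] <- img
    }
  }
  if (noise) frames[] <- rpois(length(frames), frames)
  if (max(frames) > 65535) {
    warning("rendered intensities exceed 16-bit range; clipping at 65535")
    frames[frames > 65535] <- 65535
  }
  spt_movie(frames, config$pixel_size, config$frame_interval)
}

#' Write / read a movie as multi-page TIFF with a JSON metadata sidecar
#'
#' The TIFF stores 16-bit frames; the sidecar (`<path>.json`) records
#' `pixel_size_um`, `frame_interval_s` and optionally the generator seed, so
#' the physical calibration travels with the file.
#'
#' @param movie An [spt_movie()].
#' @param path Output TIFF path.
#' @param seed Optional integer recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, seed = NULL) {
  stopifnot(inherits(movie, "spt_movie"))
  nfr <- dim(movie$frames)[3]
  pages <- lapply(seq_len(nfr), function(f)
    pmin(pmax(movie$frames[, , f], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(pixel_size_um = movie$pixel_size,
               frame_interval_s = movie$frame_interval)
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param pixel_size,frame_interval Calibration used if no sidecar is found.
#' @export
read_movie_tiff <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    frames[, , f] <- pg * 65535
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    pixel_size <- pixel_size %||% meta$pixel_size_um
    frame_interval <- frame_interval %||% meta$frame_interval_s
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("no metadata sidecar found; supply `pixel_size` and `frame_interval`",
         call. = FALSE)
  spt_movie(frames, pixel_size, frame_interval)
}
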