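# Sub-pixel Gaussian localization ------------------------------------------

#' Fit a 2D Gaussian around a candidate pixel
#'
#' Least-squares fit of an isotropic 2D Gaussian (amplitude, sub-pixel
#' center, sigma, constant offset) to the pixel window around a detected
#' candidate, giving the super-localized position in micrometres. Windows
#' that would extend past the frame are shrunk and the record flagged; fits
#' that do not converge, or whose sigma falls outside `[0.5, 5]` px, are
#' rejected with a reason.
#'
#' @param frame Numeric matrix.
#' @param candidate List or one-row data.frame with integer `row`, `col`.
#' @param window_halfwidth Half-width of the square fit window in px
#'   (default 3, i.e. a 7x7 window).
#' @param pixel_size Pixel size (um/px) used to convert to micrometres.
#' @return A one-row `data.frame(x_um, y_um, intensity, sigma_um, quality,
#'   converged, truncated, reject_reason)`; `quality` is the fitted
#'   amplitude over the residual SD. `NULL` is never returned; inspect
#'   `converged`.
#' @export
fit_gaussian <- function(frame, candidate, window_halfwidth = 3L,
                         pixel_size = 1) {
  r0 <- as.integer(candidate$row[1]); c0 <- as.integer(candidate$col[1])
  h <- as.integer(window_halfwidth)
  nr <- nrow(frame); nc <- ncol(frame)
  rows <- max(1L, r0 - h):min(nr, r0 + h)
  cols <- max(1L, c0 - h):min(nc, c0 + h)
  truncated <- length(rows) < 2 * h + 1 || length(cols) < 2 * h + 1
  win <- frame[rows, cols, drop = FALSE]
  # coordinates of window pixels in 0-based pixel units
  py <- matrix(rows - 1, length(rows), length(cols))
  px <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
  off0 <- min(win); amp0 <- max(win) - off0
  reject <- function(reason) data.frame(
    x_um = NA_real_, y_um = NA_real_, intensity = NA_real_,
    sigma_um = NA_real_, quality = NA_real_, converged = FALSE,
    truncated = truncated, reject_reason = reason)
  if (amp0 <= 0) return(reject("flat window"))
  w <- win - off0
  x0 <- sum(px * w) / sum(w); y0 <- sum(py * w) / sum(w)
  par0 <- c(log(amp0), x0, y0, log(1.3), off0)
  model <- function(p) p[5] + exp(p[1]) *
    exp(-((px - p[2])^2 + (py - p[3])^2) / (2 * exp(2 * p[4])))
  obj <- function(p) sum((model(p) - win)^2)
  fit <- tryCatch(optim(par0, obj, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10)),
                  error = function(e) NULL)
  if (is.null(fit)) return(reject("optimizer error"))
  p <- fit$par
  sigma_px <- exp(p[4])
  if (sigma_px < 0.5 || sigma_px > 5) return(reject("sigma out of [0.5, 5] px"))
  cx <- p[2]; cy <- p[3]
  if (cx < min(px) - 1 || cx > max(px) + 1 || cy < min(py) - 1 ||
      cy > max(py) + 1) return(reject("center outside window"))
  resid_sd <- sqrt(fit$value / length(win))
  data.frame(x_um = cx * pixel_size, y_um = cy * pixel_size,
             intensity = exp(p[1]) * 2 * pi * sigma_px^2,
             sigma_um = sigma_px * pixel_size,
             quality = exp(p[1]) / max(resid_sd, .Machine$double.eps),
             converged = TRUE, truncated = truncated,
             reject_reason = NA_character_)
}

#' Super-localize every frame of a movie
#'
#' Runs [detect_spots()] and [fit_gaussian()] on each frame and returns the
#' retained (converged) localizations in micrometres.
#'
#' @param movie An [spt_movie()].
#' @inheritParams detect_spots
#' @inheritParams fit_gaussian
#' @return `data.frame(frame, x_um, y_um, intensity, sigma_um, quality)`
#'   with 0-based frames, sorted by frame.
#' @export
localize_movie <- function(movie, detection_scale = 2L, threshold_k = 3,
                           window_halfwidth = 3L) {
  stopifnot(inherits(movie, "spt_movie"))
  nf <- dim(movie$frames)[3]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    cand <- detect_spots(movie$frames[, , f], detection_scale, threshold_k)
    if (nrow(cand) == 0) next
    locs <- do.call(rbind, lapply(seq_len(nrow(cand)), function(k)
      fit_gaussian(movie$frames[, , f], cand[k, ], window_halfwidth,
                   movie$pixel_size)))
    locs <- locs[locs$converged, , drop = FALSE]
    if (nrow(locs) == 0) next
    out[[f]] <- data.frame(frame = f - 1L, locs[, c("x_um", "y_um",
                                                    "intensity", "sigma_um",
                                                    "quality")])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), sigma_um = numeric(),
                      quality = numeric())
  res
}
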