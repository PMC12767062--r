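# Spot detection -----------------------------------------------------------

#' Rolling-average preprocessing of a movie
#'
#' Replaces each frame by the mean of a centered window of frames (default
#' 3-frame rolling average, the preprocessing used for low-SNR in-vivo
#' movies). Edge frames use truncated windows. Metadata is preserved.
#'
#' @param movie An [spt_movie()].
#' @param rolling_window Odd window length >= 1.
#' @return The smoothed [spt_movie()].
#' @export
preprocess_movie <- function(movie, rolling_window = 3L) {
  stopifnot(inherits(movie, "spt_movie"))
  w <- as.integer(rolling_window)
  if (w < 1 || w %% 2 == 0)
    stop("`rolling_window` must be odd and >= 1", call. = FALSE)
  nf <- dim(movie$frames)[3]
  if (w > nf)
    stop("`rolling_window` exceeds the number of frames", call. = FALSE)
  if (w == 1) return(movie)
  half <- (w - 1L) %/% 2L
  out <- movie$frames
  for (f in seq_len(nf)) {
    idx <- max(1L, f - half):min(nf, f + half)
    out[, , f] <- apply(movie$frames[, , idx, drop = FALSE], c(1, 2), mean)
  }
  spt_movie(out, movie$pixel_size, movie$frame_interval)
}

# separable convolution with the B3-spline kernel dilated by `step`,
# replicated edges (a-trous scheme)
atrous_smooth <- function(img, step) {
  k <- c(1, 4, 6, 4, 1) / 16
  off <- c(-2L, -1L, 0L, 1L, 2L) * step
  nr <- nrow(img); nc <- ncol(img)
  # rows
  tmp <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    idx <- pmin(pmax(seq_len(nr) + off[j], 1L), nr)
    tmp <- tmp + k[j] * img[idx, , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    idx <- pmin(pmax(seq_len(nc) + off[j], 1L), nc)
    out <- out + k[j] * tmp[, idx, drop = FALSE]
  }
  out
}

# 8-connected labeling of a logical matrix (two-pass flood fill via BFS)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L
      c <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  list(labels = lab, n = cur)
}

#' Detect candidate spots in a single frame
#'
#' A-trous B3-spline wavelet detection: the wavelet band at
#' `detection_scale` (difference between successive B3-spline smoothings) is
#' thresholded at `threshold_k` times its robust noise SD (1.4826 x MAD);
#' each surviving 8-connected region contributes its band-intensity maximum
#' as one candidate.
#'
#' @param frame Numeric matrix (single movie frame).
#' @param detection_scale Wavelet scale (>= 1); scale 2 suits PSF-sized
#'   spots on a Nyquist-sampled camera.
#' @param threshold_k Threshold in robust-noise-SD units (default 3).
#' @param min_area Minimum pixel count of a surviving band region (default
#'   3); single-pixel noise spikes are not PSF-shaped and are discarded.
#' @return `data.frame(row, col, band)` of candidate pixels (integer pixel
#'   indices, 1-based) and their band intensity; empty for blank frames.
#' @export
detect_spots <- function(frame, detection_scale = 2L, threshold_k = 3,
                         min_area = 3L) {
  stopifnot(is.matrix(frame), detection_scale >= 1)
  prev <- frame
  band <- NULL
  for (s in seq_len(detection_scale)) {
    sm <- atrous_smooth(prev, 2L^(s - 1L))
    band <- prev - sm
    prev <- sm
  }
  noise_sd <- mad(band)
  if (noise_sd == 0) return(data.frame(row = integer(), col = integer(),
                                       band = numeric()))
  mask <- band > threshold_k * noise_sd
  if (!any(mask)) return(data.frame(row = integer(), col = integer(),
                                    band = numeric()))
  lab <- label_components(mask)
  out <- lapply(seq_len(lab$n), function(l) {
    px <- which(lab$labels == l)
    if (length(px) < min_area) return(NULL)
    best <- px[which.max(band[px])]
    nr <- nrow(frame)
    data.frame(row = ((best - 1L) %% nr) + 1L,
               col = ((best - 1L) %/% nr) + 1L,
               band = band[best])
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(row = integer(), col = integer(),
                                      band = numeric())
  res
}
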