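# Extracellular-matrix mask metrics ----------------------------------------

#' Percent signal area within an ROI
#'
#' `100 * foreground pixels inside the ROI / ROI pixels`; the percent-area
#' quantification of thresholded matrix staining.
#'
#' @param mask Binary signal mask.
#' @param roi Binary ROI mask of the same dimension; `NULL` for the whole
#'   image.
#' @return Percent (0-100).
#' @export
percent_area <- function(mask, roi = NULL) {
  if (is.null(roi)) roi <- matrix(1, nrow(mask), ncol(mask))
  stopifnot(all(dim(mask) == dim(roi)))
  n_roi <- sum(roi > 0)
  if (n_roi == 0) stop("empty ROI", call. = FALSE)
  100 * sum(mask > 0 & roi > 0) / n_roi
}

# 8-neighborhood values P2..P9 (clockwise from north) for all pixels
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Topology-preserving skeletonization (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels in two alternating sub-iterations
#' until the mask is one pixel wide, preserving connectivity (a solid bar
#' thins to a line, a ring to a single-pixel closed loop).
#'
#' @param mask Binary matrix.
#' @return Binary skeleton matrix.
#' @export
skeletonize <- function(mask) {
  m <- (mask > 0) * 1
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      # (p2 = north neighbor in matrix terms: row - 1 seen from the pixel;
      # orientation is immaterial to the thinning conditions)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0, nrow(m), ncol(m))
      for (k in 1:8) a <- a + (seqs[[k]] == 0 & seqs[[k + 1]] == 1)
      if (sub == 1) {
        c1 <- p2 * p4 * p6; c2 <- p4 * p6 * p8
      } else {
        c1 <- p2 * p4 * p8; c2 <- p2 * p6 * p8
      }
      del <- m == 1 & b >= 2 & b <= 6 & a == 1 & c1 == 0 & c2 == 0
      if (any(del)) { m[del] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

#' Box-counting fractal dimension of a binary mask
#'
#' Counts occupied boxes N(s) over dyadic box sizes `s = 2, 4, ..., side/4`
#' (grid anchored at the mask origin) and returns minus the OLS slope of
#' `log N` versus `log s`. An empty mask scores 0 by convention (the regime
#' of matrix-free amyloid cores). A straight line scores ~1, a filled plane
#' ~2.
#'
#' @param mask Binary matrix with min(side) >= 64 px.
#' @param offsets Number of random grid offsets to average over (default 0:
#'   single origin-anchored grid).
#' @return Fractal dimension (>= 0).
#' @export
box_count_fractal <- function(mask, offsets = 0L) {
  side <- min(dim(mask))
  if (side < 64) stop("mask side must be >= 64 px", call. = FALSE)
  if (sum(mask > 0) == 0) return(0)
  sizes <- 2^(1:floor(log2(side / 4)))
  count_boxes <- function(m, s, off_r = 0L, off_c = 0L) {
    fg <- which(m > 0, arr.ind = TRUE)
    br <- (fg[, 1] - 1 + off_r) %/% s
    bc <- (fg[, 2] - 1 + off_c) %/% s
    length(unique(br * (max(bc) + 1L + 1L) + bc))
  }
  n <- vapply(sizes, function(s) {
    if (offsets <= 0) return(as.numeric(count_boxes(mask, s)))
    mean(vapply(seq_len(offsets), function(i)
      count_boxes(mask, s, sample.int(s, 1) - 1L, sample.int(s, 1) - 1L),
      numeric(1)))
  }, numeric(1))
  fit <- lm(log(n) ~ log(sizes))
  max(-unname(coef(fit)[2]), 0)
}

#' Mean gray value within an ROI
#'
#' Arithmetic mean of pixel values inside the ROI; for a list of slices the
#' per-slice means are averaged (multi-slice quantification).
#'
#' @param image Numeric matrix, or a list of matrices (slices).
#' @param roi Binary ROI mask (`NULL` = whole image).
#' @return Mean gray value.
#' @export
mean_intensity <- function(image, roi = NULL) {
  if (is.list(image))
    return(mean(vapply(image, mean_intensity, numeric(1), roi = roi)))
  if (is.null(roi)) roi <- matrix(1, nrow(image), ncol(image))
  stopifnot(all(dim(image) == dim(roi)))
  if (sum(roi > 0) == 0) stop("empty ROI", call. = FALSE)
  mean(image[roi > 0])
}

#' Matrix metrics of a stained image within ROIs
#'
#' Thresholds the image (isodata by default), optionally skeletonizes the
#' mask (the default for the fractal dimension, since skeletonization
#' precedes the fractal analysis in the reference workflow), and reports
#' per-ROI percent area, fractal dimension and mean intensity.
#'
#' @param image Numeric matrix.
#' @param rois Named list of binary ROI masks (`NULL` = whole image).
#' @param threshold Numeric threshold, or `"isodata"`.
#' @param fractal_on One of `"skeleton"` (default) or `"mask"`.
#' @return `data.frame(roi, percent_area, fractal_dim, mean_intensity,
#'   threshold, fractal_on)`.
#' @export
matrix_metrics <- function(image, rois = NULL, threshold = "isodata",
                           fractal_on = c("skeleton", "mask")) {
  fractal_on <- match.arg(fractal_on)
  thr <- if (identical(threshold, "isodata")) isodata_threshold(image)
         else threshold
  mask <- (image > thr) * 1
  if (is.null(rois)) rois <- list(full = matrix(1, nrow(image), ncol(image)))
  out <- lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    sub <- mask * (roi > 0)
    frac_input <- if (fractal_on == "skeleton") skeletonize(sub) else sub
    data.frame(roi = nm,
               percent_area = percent_area(mask, roi),
               fractal_dim = box_count_fractal(frac_input),
               mean_intensity = mean_intensity(image, roi),
               threshold = thr, fractal_on = fractal_on)
  })
  do.call(rbind, out)
}
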