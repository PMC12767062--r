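# Plaque morphometry: projection, thresholding, circularity ----------------

#' Maximum-intensity z-projection
#'
#' Pixel-wise maximum over the optical slices of a stack (the projection
#' applied to confocal z-stacks, typically 10 slices, before plaque
#' segmentation).
#'
#' @param stack 3D array `[rows, cols, slices]` or a list of matrices.
#' @param n_slices Optional number of leading slices to project.
#' @return A matrix.
#' @export
max_projection <- function(stack, n_slices = NULL) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) == 2) return(stack)
  stopifnot(length(dim(stack)) == 3, dim(stack)[3] >= 1)
  if (!is.null(n_slices))
    stack <- stack[, , seq_len(min(n_slices, dim(stack)[3])), drop = FALSE]
  apply(stack, c(1, 2), max)
}

#' Isodata (Ridler-Calvard) threshold
#'
#' Iterative intermeans threshold: the fixed point of
#' `T = (mean(values below T) + mean(values above T)) / 2`, the "isodata"
#' global threshold of ImageJ. Adding a constant to the image shifts the
#' threshold by the same constant.
#'
#' @param image Numeric matrix or vector (must not be constant).
#' @param tol Convergence tolerance.
#' @return The threshold value (foreground = values strictly above it).
#' @export
isodata_threshold <- function(image, tol = 1e-6) {
  v <- as.numeric(image)
  if (max(v) == min(v)) stop("image is constant; no threshold exists",
                             call. = FALSE)
  t_old <- -Inf
  t <- mean(v)
  for (i in 1:500) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) return(t_new)
    t <- t_new
  }
  t
}

#' Wand selection: 8-connected component containing a seed
#'
#' Reproduces the wand-tracing selection on a thresholded image: the
#' 8-connected foreground component containing the seed pixel
#' (diagonal-touching pixels are connected).
#'
#' @param mask Binary matrix.
#' @param seed Integer `c(row, col)` of a foreground pixel.
#' @return Binary matrix of the selected component.
#' @export
wand_select <- function(mask, seed) {
  stopifnot(length(seed) == 2)
  m <- mask > 0
  if (!m[seed[1], seed[2]])
    stop("seed lies on background", call. = FALSE)
  lab <- label_components(m)
  (lab$labels == lab$labels[seed[1], seed[2]]) * 1
}

# perimeter of the largest 0.5-level boundary polygon of a mask
# (polygon through pixel-edge midpoints with 45-degree corner cutting)
mask_perimeter <- function(mask) {
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- (mask > 0) * 1
  cl <- contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = m,
                     levels = 0.5)
  if (length(cl) == 0) return(NA_real_)
  lens <- vapply(cl, function(p) {
    x <- c(p$x, p$x[1]); y <- c(p$y, p$y[1])  # close the polygon
    sum(sqrt(diff(x)^2 + diff(y)^2))
  }, numeric(1))
  max(lens)
}

#' Circularity of a plaque mask
#'
#' The shape descriptor `C = 4 * pi * area / perimeter^2`: 1 for a perfect
#' circle, small for filamentous shapes. Area is the foreground pixel count
#' (times `pixel_size^2`; the descriptor is scale-free so the default pixel
#' units suffice), and the perimeter is estimated from the 0.5-level
#' boundary polygon through pixel-edge midpoints (45-degree corner cutting),
#' taking the longest (outer) boundary; holes are ignored, matching a
#' wand-style selection. A single-pixel component is defined through its
#' unit-square boundary (`C = 4 * pi / 16`) and flagged with a warning. C
#' is not clipped at 1 by default (discretization can push it slightly
#' above).
#'
#' @param mask Binary matrix containing one connected component.
#' @param clip Clip the result at 1 (default `FALSE`).
#' @return Circularity (dimensionless).
#' @export
circularity <- function(mask, clip = FALSE) {
  A <- sum(mask > 0)
  if (A == 0) stop("empty mask", call. = FALSE)
  if (A == 1) {
    warning("single-pixel component; circularity from its unit-square boundary")
    P <- 4
  } else {
    P <- mask_perimeter(mask)
  }
  C <- 4 * pi * A / P^2
  if (clip) C <- min(C, 1)
  C
}

#' Classify a plaque phenotype from its circularity
#'
#' Filamentous plaques score 0.00-0.14, intermediate above 0.14 and up to
#' 0.28, compact strictly above 0.28.
#'
#' @param C Circularity value(s), >= 0.
#' @return Character vector in `{filamentous, intermediate, compact}`.
#' @export
classify_phenotype <- function(C) {
  stopifnot(all(C >= 0))
  ifelse(C <= ECS_CIRC_FILAMENTOUS_MAX, "filamentous",
         ifelse(C <= ECS_CIRC_INTERMEDIATE_MAX, "intermediate", "compact"))
}

#' Log-normality check of plaque areas
#'
#' Tests whether `log(areas)` is consistent with a normal distribution
#' using a stock omnibus normality test (Anderson-Darling,
#' [nortest::ad.test()]); the sample passes when `p > alpha`.
#'
#' @param areas Positive areas (n >= 8).
#' @param alpha Significance level (default 0.05).
#' @return List with `pass` (logical), `statistic`, `p_value`, `method`.
#' @export
lognormality_check <- function(areas, alpha = 0.05) {
  if (length(areas) < 8) stop("need at least 8 areas", call. = FALSE)
  if (any(areas <= 0)) stop("areas must be positive", call. = FALSE)
  ht <- nortest::ad.test(log(areas))
  list(pass = ht$p.value > alpha, statistic = unname(ht$statistic),
       p_value = ht$p.value, method = ht$method)
}

#' Full morphometry of one plaque mask
#'
#' Convenience wrapper: area, equivalent radius, circularity and phenotype
#' of a segmented plaque component.
#'
#' @param mask Binary matrix (single component).
#' @param pixel_size um/px.
#' @return One-row data.frame with `area_um2`, `radius_um`, `circularity`,
#'   `phenotype`.
#' @export
plaque_morphometry <- function(mask, pixel_size = 1) {
  A <- sum(mask > 0) * pixel_size^2
  C <- circularity(mask)
  data.frame(area_um2 = A, radius_um = area_to_radius(A),
             circularity = C, phenotype = classify_phenotype(C))
}
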