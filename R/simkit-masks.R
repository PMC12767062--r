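# Synthetic plaque and matrix masks ----------------------------------------

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# binary dilation with a disc brush (EBImage)
dilate_mask <- function(mask, radius_px) {
  if (radius_px < 1) return(mask)
  sz <- 2 * floor(radius_px) + 1
  br <- EBImage::makeBrush(sz, shape = "disc")
  out <- EBImage::dilate(EBImage::Image(mask), br)
  m <- EBImage::imageData(out)
  storage.mode(m) <- "double"
  (m > 0) * 1
}

# star-shaped blob: pixel is foreground iff its radius <= r(theta)
raster_blob <- function(size, center, r_fun) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dy <- rows - center[1]; dx <- cols - center[2]
  th <- atan2(dy, dx)
  (sqrt(dx^2 + dy^2) <= r_fun(th)) * 1
}

draw_filament_skeleton <- function(size) {
  mask <- matrix(0, size, size)
  ctr <- c(size / 2, size / 2)
  n_branch <- sample(4:7, 1)
  for (b in seq_len(n_branch)) {
    pos <- ctr
    ang <- runif(1, 0, 2 * pi)
    len <- round(runif(1, 0.25, 0.45) * size)
    for (s in seq_len(len)) {
      ang <- ang + rnorm(1, 0, 0.25)
      pos <- pos + c(sin(ang), cos(ang))
      r <- round(pos[1]); c <- round(pos[2])
      if (r < 2 || c < 2 || r > size - 1 || c > size - 1) break
      mask[r, c] <- 1
      # sprouting side branches keeps the shape dendritic
      if (s > 10 && runif(1) < 0.01) {
        ang2 <- ang + sample(c(-1, 1), 1) * runif(1, 0.8, 1.6)
        p2 <- pos
        for (t in seq_len(round(len / 2))) {
          ang2 <- ang2 + rnorm(1, 0, 0.25)
          p2 <- p2 + c(sin(ang2), cos(ang2))
          r2 <- round(p2[1]); c2 <- round(p2[2])
          if (r2 < 2 || c2 < 2 || r2 > size - 1 || c2 > size - 1) break
          mask[r2, c2] <- 1
        }
      }
    }
  }
  mask
}

#' Generate a plaque mask of a requested circularity phenotype
#'
#' Draws a random binary plaque mask whose measured circularity (via
#' [circularity()]) falls in the requested class: a near-circular blob for
#' `compact` (C > 0.28), a dilated branched skeleton for `filamentous`
#' (C <= 0.14), and a strongly lobed blob for `intermediate`
#' (0.14 < C <= 0.28). The generator draws and re-measures until the class
#' matches, up to `max_tries` attempts.
#'
#' @param target_class One of `"filamentous"`, `"intermediate"`, `"compact"`.
#' @param size Mask side length in pixels (default 256).
#' @param seed Optional integer seed (caller RNG state is restored).
#' @param max_tries Bounded retry count (error when exhausted).
#' @return Binary matrix (0/1) of dimension `size x size`.
#' @export
generate_plaque_mask <- function(target_class, size = 256L, seed = NULL,
                                 max_tries = 60L) {
  target_class <- match.arg(target_class,
                            c("filamentous", "intermediate", "compact"))
  with_seed(seed, {
    amp <- 0.35  # lobe amplitude for intermediate shapes, adapted on retry
    for (try in seq_len(max_tries)) {
      ctr <- c(size / 2, size / 2)
      mask <- switch(target_class,
        compact = {
          r0 <- runif(1, 0.15, 0.22) * size
          e <- runif(1, 0, 0.25)
          ph <- runif(1, 0, 2 * pi)
          raster_blob(size, ctr, function(th) r0 * (1 + e * cos(2 * (th - ph))))
        },
        intermediate = {
          r0 <- runif(1, 0.16, 0.22) * size
          k <- sample(c(7L, 8L, 9L), 1)
          ph <- runif(3, 0, 2 * pi)
          a2 <- runif(1, 0.05, 0.12)
          raster_blob(size, ctr, function(th)
            pmax(r0 * (1 + amp * cos(k * (th - ph[1])) +
                         a2 * cos(3 * (th - ph[2]))), 2))
        },
        filamentous = dilate_mask(draw_filament_skeleton(size), 1))
      if (sum(mask) < 9) next
      C <- circularity(mask)
      if (classify_phenotype(C) == target_class) return(mask)
      if (target_class == "intermediate")
        amp <- amp * if (C > ECS_CIRC_INTERMEDIATE_MAX) 1.2 else 0.85
    }
    stop(sprintf("could not generate a '%s' mask in %d tries",
                 target_class, max_tries), call. = FALSE)
  })
}

#' Generate a synthetic extracellular-matrix mask
#'
#' Emulates thresholded matrix-staining images: `intact` produces a dense
#' reticular network (thresholded smoothed random field; its skeleton has a
#' box-counting fractal dimension around 1.5-1.7), `degraded` sparse
#' disconnected fragments, and `empty` an all-zero mask (the regime inside
#' amyloid cores, where matrix signal is absent).
#'
#' @param condition One of `"intact"`, `"degraded"`, `"empty"`.
#' @param size Mask side (pixels, >= 64).
#' @param seed Optional integer seed.
#' @return Binary matrix (0/1).
#' @export
generate_matrix_mask <- function(condition, size = 128L, seed = NULL) {
  condition <- match.arg(condition, c("intact", "degraded", "empty"))
  if (size < 64) stop("`size` must be >= 64 px", call. = FALSE)
  if (condition == "empty") return(matrix(0, size, size))
  with_seed(seed, {
    noise <- matrix(rnorm(size * size), size, size)
    sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(noise),
                                            sigma = if (condition == "intact") 1.2 else 2.5))
    cut <- quantile(sm, if (condition == "intact") 0.55 else 0.95)
    (sm > cut) * 1
  })
}
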