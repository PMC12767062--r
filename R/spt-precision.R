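# Localization precision from immobile emitters ----------------------------

#' Estimate localization precision from an immobile emitter
#'
#' The pointing precision of the setup is the standard deviation of the
#' repeatedly localized position of an immobile emitter (about 50 frames in
#' practice): `sigma_x` and `sigma_y` are the coordinate SDs and
#' `sigma_mean` their average, the precision value fed into the
#' diffusion-error model [dinst_error()].
#'
#' The trajectory must first classify as immobile: the median of its
#' windowed (sliding 10-frame) D_inst must fall below the mobility
#' threshold. Passing a mobile trajectory is an error, since its spread
#' would measure motion, not precision.
#'
#' @param trajectory Table with `frame`, `x_um`, `y_um` of one emitter.
#' @param frame_interval Frame interval (s), used for the mobility check.
#' @param threshold Mobility threshold (um^2/s).
#' @return List of class `precision_estimate`: `sigma_x`, `sigma_y`,
#'   `sigma_mean` (um) and `n_frames`.
#' @export
estimate_precision <- function(trajectory, frame_interval,
                               threshold = ECS_IMMOBILE_THRESHOLD) {
  stopifnot(nrow(trajectory) >= 3)
  # mobility check on the median windowed D: robust against the large
  # per-fit error that localization noise induces in a single global fit
  med_D <- if (nrow(trajectory) >= 10 && all(diff(trajectory$frame) == 1)) {
    median(sliding_dinst(trajectory, frame_interval)$local_D)
  } else {
    msd <- compute_msd(trajectory, frame_interval)
    fit_dinst(msd, min(4L, nrow(msd)))$D_inst
  }
  fit <- list(D_inst = med_D)
  if (!is.na(fit$D_inst) &&
      classify_mobility(fit$D_inst, threshold) == "mobile")
    stop(sprintf(
      "trajectory is mobile (D_inst = %.4g um^2/s >= %.4g); precision is only defined for immobile emitters",
      fit$D_inst, threshold), call. = FALSE)
  sx <- sd(trajectory$x_um)
  sy <- sd(trajectory$y_um)
  structure(list(sigma_x = sx, sigma_y = sy, sigma_mean = (sx + sy) / 2,
                 n_frames = nrow(trajectory)),
            class = "precision_estimate")
}
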