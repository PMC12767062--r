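# Simulation configuration and motion models -------------------------------

#' Simulation configuration
#'
#' Bundles the acquisition constants used by the synthetic-data generator:
#' camera geometry, frame rate, PSF width, photon budget and (for
#' point-process simulations) an explicit localization jitter.
#'
#' Defaults mirror the quantum-dot acquisition regime: 28 Hz sampling, and a
#' camera with 160 nm pixels and a 130 nm PSF sigma so the PSF is
#' Nyquist-sampled. The elongated-probe (nanotube) regime uses
#' `frame_interval = 0.033`.
#'
#' @param seed Integer seed for the generator's RNG stream.
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param frame_interval Frame interval in seconds (> 0); 1/28 s by default.
#' @param n_frames Number of frames per movie (positive integer).
#' @param field_size Integer vector `c(height_px, width_px)` of the camera
#'   field.
#' @param psf_sigma Gaussian PSF standard deviation in micrometres (> 0).
#' @param photon_rate Expected photons per frame per emitter (>= 0).
#' @param background Background photons per pixel per frame (>= 0).
#' @param localization_jitter Standard deviation (um, >= 0) of Gaussian
#'   observation noise added per axis in point-process-only simulations
#'   (i.e. when trajectories are observed directly rather than rendered).
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_frames = 60)
#' cfg$frame_interval * cfg$n_frames  # movie duration in seconds
#' @export
sim_config <- function(seed = 1L,
                       pixel_size = 0.160,
                       frame_interval = 1 / 28,
                       n_frames = 60L,
                       field_size = c(128L, 128L),
                       psf_sigma = 0.130,
                       photon_rate = 2000,
                       background = 10,
                       localization_jitter = 0.030) {
  stopifnot(length(seed) == 1, is.finite(seed))
  check_pos <- function(x, name) {
    if (length(x) != 1 || !is.finite(x) || x <= 0)
      stop(sprintf("`%s` must be a single strictly positive finite number", name),
           call. = FALSE)
  }
  check_nonneg <- function(x, name) {
    if (length(x) != 1 || !is.finite(x) || x < 0)
      stop(sprintf("`%s` must be a single non-negative finite number", name),
           call. = FALSE)
  }
  check_pos(pixel_size, "pixel_size")
  check_pos(frame_interval, "frame_interval")
  check_pos(psf_sigma, "psf_sigma")
  check_nonneg(photon_rate, "photon_rate")
  check_nonneg(background, "background")
  check_nonneg(localization_jitter, "localization_jitter")
  if (length(n_frames) != 1 || n_frames < 1 || n_frames != round(n_frames))
    stop("`n_frames` must be a positive integer", call. = FALSE)
  if (length(field_size) != 2 || any(field_size < 1) ||
      any(field_size != round(field_size)))
    stop("`field_size` must be two positive integers (height_px, width_px)",
         call. = FALSE)
  structure(
    list(seed = as.integer(seed), pixel_size = pixel_size,
         frame_interval = frame_interval, n_frames = as.integer(n_frames),
         field_size = as.integer(field_size), psf_sigma = psf_sigma,
         photon_rate = photon_rate, background = background,
         localization_jitter = localization_jitter),
    class = "sim_config")
}

#' Per-region motion model
#'
#' Describes Brownian motion inside one labeled region: a diffusion
#' coefficient, an optional circular confinement domain, and the probability
#' that a particle born in the region is immobile.
#'
#' @param D Diffusion coefficient in um^2/s (>= 0).
#' @param confinement_radius Radius (um) of a reflecting circular domain the
#'   particle is confined to, or `Inf` for unconfined motion.
#' @param immobile_probability Fraction in `[0, 1]` of particles that are
#'   immobile (simulated with D = 0; observation jitter is only added at
#'   rendering or observation time).
#'
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(D, confinement_radius = Inf, immobile_probability = 0) {
  if (!is.finite(D) || D < 0) stop("`D` must be finite and >= 0", call. = FALSE)
  if (is.na(confinement_radius) ||
      (is.finite(confinement_radius) && confinement_radius <= 0))
    stop("`confinement_radius` must be > 0 when finite", call. = FALSE)
  if (!is.finite(immobile_probability) || immobile_probability < 0 ||
      immobile_probability > 1)
    stop("`immobile_probability` must lie in [0, 1]", call. = FALSE)
  structure(list(D = D, confinement_radius = confinement_radius,
                 immobile_probability = immobile_probability),
            class = "motion_model")
}

# field extent in micrometres: c(width_um, height_um); x = column axis
field_extent_um <- function(config) {
  rev(config$field_size) * config$pixel_size
}
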