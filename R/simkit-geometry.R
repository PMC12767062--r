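# Synthetic plaque geometry ------------------------------------------------

#' Sample a synthetic plaque geometry
#'
#' Draws an amyloid-core area from a log-normal distribution (cortical core
#' areas are log-normally distributed; the ex-vivo median is 134.2 um^2),
#' converts it to an equivalent-circle radius via `A = pi * r^2`, and builds
#' the concentric Ring and Out regions. The Ring width equals
#' `ring_factor` times the core radius (median ratio 1.82), and the Out
#' region extends to `out_factor` times the ring outer radius.
#'
#' @param config A [sim_config()]; the geometry must fit inside its field.
#' @param core_area_median Median core area in um^2 (> 0).
#' @param core_area_sigma_log Standard deviation of `log(area)` (>= 0); 0
#'   gives a deterministic core of exactly the median area.
#' @param ring_factor Ratio of ring width to core radius (default 1.82).
#' @param out_factor Out outer radius as a multiple of the ring outer radius
#'   (default 2); clipping to the field is handled downstream.
#' @param center Plaque center in um `c(x, y)`; defaults to the field center.
#'
#' @return An object of class `plaque_geometry`: list with `center`,
#'   `core_radius`, `ring_outer_radius`, `out_outer_radius` (all um) and
#'   `core_area` (um^2).
#' @examples
#' cfg <- sim_config(seed = 1, field_size = c(512, 512))
#' g <- sample_plaque_geometry(cfg, core_area_median = 134.2,
#'                             core_area_sigma_log = 0)
#' g$core_radius  # sqrt(134.2 / pi) = 6.54 um
#' @export
sample_plaque_geometry <- function(config,
                                   core_area_median = 134.2,
                                   core_area_sigma_log = 0.8,
                                   ring_factor = ECS_RING_FACTOR,
                                   out_factor = 2,
                                   center = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (core_area_median <= 0) stop("`core_area_median` must be > 0", call. = FALSE)
  if (core_area_sigma_log < 0) stop("`core_area_sigma_log` must be >= 0", call. = FALSE)
  if (ring_factor <= 0) stop("`ring_factor` must be > 0", call. = FALSE)
  ext <- field_extent_um(config)
  if (is.null(center)) center <- ext / 2
  area <- rlnorm(1, meanlog = log(core_area_median), sdlog = core_area_sigma_log)
  r <- area_to_radius(area)
  ring_outer <- r * (1 + ring_factor)
  out_outer <- ring_outer * out_factor
  # geometry must fit: out annulus may be clipped later, but the ring must fit
  max_fit <- min(c(center, ext - center))
  if (ring_outer > max_fit)
    stop(sprintf(
      "plaque geometry exceeds field: ring_outer_radius %.2f um > %.2f um available",
      ring_outer, max_fit), call. = FALSE)
  structure(list(center = as.numeric(center), core_radius = r,
                 ring_outer_radius = ring_outer, out_outer_radius = out_outer,
                 core_area = area),
            class = "plaque_geometry")
}
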