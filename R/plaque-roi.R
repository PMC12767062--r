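# Concentric plaque ROIs and penetrability ---------------------------------

#' Circle-approximation helpers for plaque morphometry
#'
#' Plaque compartment surfaces are approximated by circles of equal area
#' (`A = pi r^2`). `area_to_radius()` returns the equivalent radius;
#' `ring_width()` the width of the cell-ring annulus, i.e. the difference
#' between the total (core + ring) equivalent radius and the core radius;
#' `plaque_volume_ratio()` the exact cube ratio `(R_tot / r_core)^3`, the
#' volume factor the whole plaque occupies relative to the core under the
#' spherical approximation.
#'
#' @param A,A_core,A_ring Areas (um^2, >= 0).
#' @return Radius or width in um.
#' @examples
#' area_to_radius(pi)           # 1
#' ring_width(pi, 3 * pi)       # 1
#' @export
area_to_radius <- function(A) {
  if (any(A < 0)) stop("area must be >= 0", call. = FALSE)
  sqrt(A / pi)
}

#' @rdname area_to_radius
#' @export
ring_width <- function(A_core, A_ring) {
  if (any(A_core < 0) || any(A_ring < 0))
    stop("areas must be >= 0", call. = FALSE)
  area_to_radius(A_core + A_ring) - area_to_radius(A_core)
}

#' @rdname area_to_radius
#' @param r_total,r_core Total and core equivalent radii (um).
#' @export
plaque_volume_ratio <- function(r_total, r_core) {
  stopifnot(all(r_total > 0), all(r_core > 0))
  (r_total / r_core)^3
}

#' Build concentric Amyloid / Ring / Out ROIs
#'
#' Constructs the three nested regions used for per-compartment analysis:
#' the Amyloid core, a Ring annulus whose width is `ring_factor` times the
#' core equivalent radius (default 1.82, the median ring-width to
#' core-radius ratio), and an Out annulus extending to `out_bound` (default
#' twice the ring outer radius). The core may be given parametrically
#' (`center` + `core_radius`, um) or as a binary mask with a pixel size, in
#' which case the core radius is the equivalent-area radius and the ring is
#' an isotropic dilation of the core mask by the ring width.
#'
#' @param center Core center `c(x, y)` in um (parametric form).
#' @param core_radius Core radius in um (parametric form).
#' @param core_mask Binary matrix (mask form); requires `pixel_size`.
#' @param pixel_size um/px for the mask form.
#' @param ring_factor Ring width as a multiple of the core radius.
#' @param out_bound Outer radius (um) of the Out annulus; `NULL` for twice
#'   the ring outer radius.
#' @param field Optional field extent `c(width_um, height_um)`; regions
#'   reaching past it are flagged `clipped` with a warning (mask-based areas
#'   are then measured on the clipped masks).
#' @return Object of class `plaque_roi`: list with `center`, `core_radius`,
#'   `ring_outer_radius`, `out_outer_radius`, areas per region (um^2),
#'   `clipped` flag, and for the mask form the three region masks.
#' @export
build_concentric_rois <- function(center = NULL, core_radius = NULL,
                                  core_mask = NULL, pixel_size = NULL,
                                  ring_factor = ECS_RING_FACTOR,
                                  out_bound = NULL, field = NULL) {
  if (ring_factor <= 0)
    stop("`ring_factor` must be > 0 (a zero-width ring is degenerate)",
         call. = FALSE)
  masks <- NULL
  if (!is.null(core_mask)) {
    stopifnot(!is.null(pixel_size), pixel_size > 0)
    A_core <- sum(core_mask > 0) * pixel_size^2
    if (A_core == 0) stop("empty core mask", call. = FALSE)
    r <- area_to_radius(A_core)
    w <- ring_factor * r
    px <- which(core_mask > 0, arr.ind = TRUE)
    ctr_px <- colMeans(px)                       # (row, col)
    center <- (rev(ctr_px) - 1) * pixel_size     # (x, y) um
    dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - (core_mask > 0))))
    ring_mask <- (core_mask <= 0) & (dm * pixel_size <= w)
    ring_outer <- r + w
    out_r <- out_bound %||% (2 * ring_outer)
    out_mask <- (core_mask <= 0) & !ring_mask & (dm * pixel_size <= out_r - r)
    masks <- list(Amyloid = (core_mask > 0) * 1, Ring = ring_mask * 1,
                  Out = out_mask * 1)
  } else {
    stopifnot(!is.null(center), !is.null(core_radius), core_radius > 0)
    r <- core_radius
    ring_outer <- r * (1 + ring_factor)
    out_r <- out_bound %||% (2 * ring_outer)
  }
  if (is.null(core_mask)) {
    if (out_r <= ring_outer)
      stop("`out_bound` must exceed the ring outer radius", call. = FALSE)
  }
  clipped <- FALSE
  if (!is.null(field)) {
    margin <- min(c(center, field - center))
    if (out_r > margin) {
      warning("Out ROI reaches past the field; clipped")
      clipped <- TRUE
    }
  }
  areas <- if (!is.null(masks)) {
    vapply(masks, function(m) sum(m > 0) * pixel_size^2, numeric(1))
  } else {
    c(Amyloid = pi * r^2, Ring = pi * (ring_outer^2 - r^2),
      Out = pi * (out_r^2 - ring_outer^2))
  }
  structure(list(center = center, core_radius = r,
                 ring_outer_radius = ring_outer, out_outer_radius = out_r,
                 ring_factor = ring_factor, areas = areas,
                 clipped = clipped, masks = masks,
                 pixel_size = pixel_size),
            class = "plaque_roi")
}

# assign points to regions; boundary points go to the inner region
assign_region <- function(points, roi) {
  if (!is.null(roi$masks)) {
    ps <- roi$pixel_size
    rr <- round(points[, 2] / ps) + 1
    cc <- round(points[, 1] / ps) + 1
    dims <- dim(roi$masks$Amyloid)
    reg <- rep(NA_character_, nrow(points))
    ok <- rr >= 1 & rr <= dims[1] & cc >= 1 & cc <= dims[2]
    idx <- cbind(rr[ok], cc[ok])
    for (name in c("Amyloid", "Ring", "Out")) {
      hit <- roi$masks[[name]][idx] > 0 & is.na(reg[ok])
      reg[ok][hit] <- name
    }
    return(reg)
  }
  d <- sqrt((points[, 1] - roi$center[1])^2 + (points[, 2] - roi$center[2])^2)
  reg <- rep(NA_character_, length(d))
  reg[d <= roi$core_radius] <- "Amyloid"
  reg[is.na(reg) & d <= roi$ring_outer_radius] <- "Ring"
  reg[is.na(reg) & d <= roi$out_outer_radius] <- "Out"
  reg
}

#' Localization density per concentric region
#'
#' Counts localizations (points, not trajectories) inside each region of a
#' [build_concentric_rois()] set and divides by the region area, the
#' "superlocalizations per unit area" statistic. A point on a shared
#' boundary is assigned to the inner region.
#'
#' @param points Two-column matrix or data.frame of `x_um`, `y_um`.
#' @param roi A `plaque_roi`.
#' @return `data.frame(region, n_locs, area_um2, density)` for Out, Ring,
#'   Amyloid.
#' @export
localization_density <- function(points, roi) {
  stopifnot(inherits(roi, "plaque_roi"))
  if (is.data.frame(points))
    points <- cbind(points$x_um %||% points[[1]],
                    points$y_um %||% points[[2]])
  points <- matrix(as.numeric(points), ncol = 2)
  reg <- if (nrow(points) > 0) assign_region(points, roi) else character(0)
  regions <- c("Out", "Ring", "Amyloid")
  data.frame(region = regions,
             n_locs = vapply(regions, function(r) sum(reg == r, na.rm = TRUE),
                             integer(1)),
             area_um2 = as.numeric(roi$areas[regions]),
             density = vapply(regions, function(r)
               sum(reg == r, na.rm = TRUE), integer(1)) /
               as.numeric(roi$areas[regions]),
             row.names = NULL)
}

#' Penetrability ratio between adjacent regions
#'
#' The localization density of the outer member divided by that of the
#' inner member (`Out/Ring` or `Ring/Amyloid`). A ratio near 1 means an
#' even distribution of points across the boundary (free exchange); large
#' ratios mean the inner compartment excludes the probe.
#'
#' @param densities Output of [localization_density()].
#' @param pair `"Out/Ring"` or `"Ring/Amyloid"`.
#' @return The density ratio, or `NA` (with a warning) when the inner
#'   density is zero.
#' @export
penetrability_ratio <- function(densities, pair = c("Out/Ring",
                                                    "Ring/Amyloid")) {
  pair <- match.arg(pair)
  members <- strsplit(pair, "/")[[1]]
  num <- densities$density[densities$region == members[1]]
  den <- densities$density[densities$region == members[2]]
  if (length(num) != 1 || length(den) != 1)
    stop("densities must contain one row per region", call. = FALSE)
  if (den == 0) {
    warning(sprintf("zero density in %s; ratio undefined", members[2]))
    return(NA_real_)
  }
  num / den
}
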