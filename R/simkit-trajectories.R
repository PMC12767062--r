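# Ground-truth Brownian trajectory simulation ------------------------------
#
# All simulators use Euler-Maruyama stepping with per-axis step SD
# sqrt(2 * D * dt); confinement is enforced by reflecting boundaries.
# Optional substepping (default 10x inside confinement domains) keeps the
# per-substep step SD small relative to the domain so that reflection is
# accurate near boundaries.

#' Simulate free 2D Brownian trajectories
#'
#' @param n Number of trajectories.
#' @param D Diffusion coefficient (um^2/s).
#' @param n_frames Frames per trajectory.
#' @param frame_interval Frame interval (s).
#' @param origin Either a single `c(x, y)` start point (um) applied to all
#'   trajectories, or a matrix with one row per trajectory, or `NULL` for
#'   origin (0, 0).
#'
#' @return A trajectory table: `data.frame(id, frame, x_um, y_um)` with
#'   0-based frames.
#' @export
simulate_free_trajectories <- function(n, D, n_frames, frame_interval,
                                       origin = NULL) {
  stopifnot(n >= 0, is.finite(D), D >= 0, n_frames >= 1, frame_interval > 0)
  if (n == 0) return(empty_trajectory_table())
  if (is.null(origin)) origin <- c(0, 0)
  org <- if (is.matrix(origin)) origin else
    matrix(origin, nrow = n, ncol = 2, byrow = TRUE)
  step_sd <- sqrt(2 * D * frame_interval)
  dx <- matrix(rnorm(n * (n_frames - 1), 0, step_sd), n, n_frames - 1)
  dy <- matrix(rnorm(n * (n_frames - 1), 0, step_sd), n, n_frames - 1)
  x <- cbind(org[, 1], org[, 1] + t(apply(dx, 1, cumsum)))
  y <- cbind(org[, 2], org[, 2] + t(apply(dy, 1, cumsum)))
  if (n_frames == 1) { x <- org[, 1, drop = FALSE]; y <- org[, 2, drop = FALSE] }
  data.frame(id = rep(seq_len(n), each = n_frames),
             frame = rep(seq_len(n_frames) - 1L, n),
             x_um = as.vector(t(x)), y_um = as.vector(t(y)))
}

# reflect radial coordinate into [r_in, r_out]; single reflection then clamp
# (valid when step SD << domain size, which substepping guarantees)
reflect_radial <- function(xy, center, r_in, r_out) {
  dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  scl <- rep(1, length(r))
  out <- r > r_out
  scl[out] <- pmax(2 * r_out - r[out], if (is.finite(r_in)) r_in else 0) / r[out]
  if (r_in > 0) {
    inn <- r < r_in & r > 0
    scl[inn] <- pmin(2 * r_in - r[inn], r_out) / r[inn]
  }
  cbind(center[1] + dx * scl, center[2] + dy * scl)
}

#' Simulate Brownian trajectories confined in reflecting disks
#'
#' Each trajectory starts uniformly inside its own reflecting circular
#' domain of radius `radius` and never leaves it. At long lag times the
#' time-averaged MSD of such a trajectory reaches the plateau
#' `E|P1 - P2|^2 = R^2` (uniform independent points in a disk), the analytic
#' identity behind the confinement-area proxy.
#'
#' @inheritParams simulate_free_trajectories
#' @param radius Confinement radius R (um).
#' @param substeps Simulation substeps per frame (default 10).
#' @param center Domain center `c(x, y)` um (shared; default origin).
#' @return Trajectory table as in [simulate_free_trajectories()].
#' @export
simulate_confined_trajectories <- function(n, D, radius, n_frames,
                                           frame_interval, substeps = 10L,
                                           center = c(0, 0)) {
  stopifnot(n >= 0, is.finite(D), D >= 0, is.finite(radius), radius > 0,
            n_frames >= 1, substeps >= 1)
  if (n == 0) return(empty_trajectory_table())
  # uniform start in the disk
  th <- runif(n, 0, 2 * pi); rr <- radius * sqrt(runif(n))
  pos <- cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
  dt_sub <- frame_interval / substeps
  step_sd <- sqrt(2 * D * dt_sub)
  x <- matrix(NA_real_, n, n_frames); y <- matrix(NA_real_, n, n_frames)
  x[, 1] <- pos[, 1]; y[, 1] <- pos[, 2]
  for (f in seq_len(n_frames - 1)) {
    for (s in seq_len(substeps)) {
      pos <- pos + matrix(rnorm(2 * n, 0, step_sd), n, 2)
      pos <- reflect_radial(pos, center, 0, radius)
    }
    x[, f + 1] <- pos[, 1]; y[, f + 1] <- pos[, 2]
  }
  data.frame(id = rep(seq_len(n), each = n_frames),
             frame = rep(seq_len(n_frames) - 1L, n),
             x_um = as.vector(t(x)), y_um = as.vector(t(y)))
}

# exact 1D reflection of coordinate z into [lo, hi] (triangle-wave folding)
fold_interval <- function(z, lo, hi) {
  w <- hi - lo
  t <- (z - lo) %% (2 * w)
  lo + ifelse(t > w, 2 * w - t, t)
}

#' Simulate trajectories diffusing along a straight channel
#'
#' Emulates an elongated probe exploring a narrow ECS channel: free Brownian
#' motion along the channel axis (x) and reflected Brownian motion across it,
#' so the transverse coordinate is uniform over the channel width at
#' stationarity. Transverse reflection uses exact triangle-wave folding, so
#' no substepping is needed for accuracy.
#'
#' @inheritParams simulate_free_trajectories
#' @param width Channel width (um); the transverse coordinate is confined to
#'   `[-width/2, width/2]`.
#' @param D_transverse Transverse diffusion coefficient (um^2/s); defaults to
#'   the longitudinal `D`.
#' @return Trajectory table as in [simulate_free_trajectories()].
#' @export
simulate_channel_trajectories <- function(n, D, width, n_frames,
                                          frame_interval,
                                          D_transverse = D) {
  stopifnot(n >= 0, width > 0, n_frames >= 1)
  if (n == 0) return(empty_trajectory_table())
  sd_l <- sqrt(2 * D * frame_interval)
  sd_t <- sqrt(2 * D_transverse * frame_interval)
  x <- matrix(rnorm(n * (n_frames - 1), 0, sd_l), n, n_frames - 1)
  x <- cbind(0, t(apply(x, 1, cumsum)))
  y0 <- runif(n, -width / 2, width / 2)
  y <- matrix(rnorm(n * (n_frames - 1), 0, sd_t), n, n_frames - 1)
  y <- cbind(y0, y0 + t(apply(y, 1, cumsum)))
  y <- fold_interval(y, -width / 2, width / 2)
  if (n_frames == 1) { x <- matrix(0, n, 1); y <- matrix(y0, n, 1) }
  data.frame(id = rep(seq_len(n), each = n_frames),
             frame = rep(seq_len(n_frames) - 1L, n),
             x_um = as.vector(t(x)), y_um = as.vector(t(y)))
}

#' Add Gaussian observation jitter to a trajectory table
#'
#' Point-process observation model: adds i.i.d. Gaussian noise of standard
#' deviation `sigma` (um) per axis to every position, emulating localization
#' noise without rendering a movie.
#'
#' @param traj Trajectory table with `x_um`, `y_um` columns.
#' @param sigma Per-axis jitter SD (um, >= 0).
#' @return The table with jittered coordinates.
#' @export
add_observation_jitter <- function(traj, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0 || nrow(traj) == 0) return(traj)
  traj$x_um <- traj$x_um + rnorm(nrow(traj), 0, sigma)
  traj$y_um <- traj$y_um + rnorm(nrow(traj), 0, sigma)
  traj
}

empty_trajectory_table <- function() {
  data.frame(id = integer(), frame = integer(),
             x_um = numeric(), y_um = numeric())
}

# uniform point in annulus [r_in, r_out] around center
runif_annulus <- function(n, center, r_in, r_out) {
  th <- runif(n, 0, 2 * pi)
  rr <- sqrt(runif(n, r_in^2, r_out^2))
  cbind(center[1] + rr * cos(th), center[2] + rr * sin(th))
}

#' Simulate ground-truth trajectories per plaque region
#'
#' Particles are born uniformly inside their region (Amyloid core, Ring
#' annulus, or Out annulus) and keep that label for life: steps are
#' reflected at the region boundary, so a trajectory never leaves the region
#' it is labeled with, mirroring the per-ROI analysis. Each region has its
#' own [motion_model()]: diffusion coefficient, optional circular confinement
#' domain (centered at the birth position and reflected along with the
#' region boundary), and an immobile subpopulation simulated with D = 0.
#'
#' For the `WT` label (no plaque), pass `geometry = NULL` and a single
#' motion model; particles then diffuse freely from uniform positions in the
#' field.
#'
#' @param geometry A [sample_plaque_geometry()] result, or `NULL` for a
#'   plaque-free (WT) field.
#' @param motion A named list of [motion_model()]s with names among
#'   `c("Out", "Ring", "Amyloid")`, or a single `motion_model` for WT.
#' @param config A [sim_config()].
#' @param n_per_region Particles per region (single integer, >= 0).
#' @param substeps Substeps per frame inside confinement domains.
#'
#' @return A ground-truth table
#'   `data.frame(id, frame, x_um, y_um, region, true_D, mobile)`.
#' @export
simulate_trajectories <- function(geometry, motion, config, n_per_region,
                                  substeps = 10L) {
  stopifnot(inherits(config, "sim_config"), n_per_region >= 0)
  nf <- config$n_frames
  if (is.null(geometry)) {
    stopifnot(inherits(motion, "motion_model"))
    motion <- list(WT = motion)
    bounds <- list(WT = c(0, Inf))
    centers <- list(WT = field_extent_um(config) / 2)
  } else {
    stopifnot(inherits(geometry, "plaque_geometry"))
    stopifnot(all(names(motion) %in% c("Out", "Ring", "Amyloid")))
    bounds <- list(Amyloid = c(0, geometry$core_radius),
                   Ring = c(geometry$core_radius, geometry$ring_outer_radius),
                   Out = c(geometry$ring_outer_radius, geometry$out_outer_radius))
    bounds <- bounds[names(motion)]
    centers <- lapply(motion, function(m) geometry$center)
  }
  out <- list()
  next_id <- 1L
  for (reg in names(motion)) {
    m <- motion[[reg]]
    if (!is.finite(m$D) || (is.finite(m$confinement_radius) &&
                            !is.finite(m$D)))
      stop("non-finite motion parameters", call. = FALSE)
    n <- n_per_region
    if (n == 0) next
    b <- bounds[[reg]]; ctr <- centers[[reg]]
    immob <- runif(n) < m$immobile_probability
    start <- if (is.finite(b[2])) runif_annulus(n, ctr, b[1], b[2]) else
      cbind(runif(n, 0, 2 * ctr[1]), runif(n, 0, 2 * ctr[2]))
    pos <- start
    x <- matrix(NA_real_, n, nf); y <- matrix(NA_real_, n, nf)
    x[, 1] <- pos[, 1]; y[, 1] <- pos[, 2]
    sub <- if (is.finite(m$confinement_radius) || is.finite(b[2]))
      as.integer(substeps) else 1L
    step_sd <- sqrt(2 * m$D * config$frame_interval / sub)
    mob_idx <- which(!immob)
    if (nf > 1 && length(mob_idx) > 0 && m$D > 0) {
      p <- pos[mob_idx, , drop = FALSE]
      for (f in seq_len(nf - 1)) {
        for (s in seq_len(sub)) {
          p <- p + matrix(rnorm(2 * length(mob_idx), 0, step_sd),
                          length(mob_idx), 2)
          if (is.finite(b[2]))
            p <- reflect_radial(p, ctr, b[1], b[2])
          if (is.finite(m$confinement_radius)) {
            for (k in seq_along(mob_idx)) {
              p[k, ] <- reflect_radial(p[k, , drop = FALSE],
                                       start[mob_idx[k], ], 0,
                                       m$confinement_radius)
            }
            if (is.finite(b[2]))
              p <- reflect_radial(p, ctr, b[1], b[2])
          }
        }
        x[mob_idx, f + 1] <- p[, 1]; y[mob_idx, f + 1] <- p[, 2]
      }
    }
    if (nf > 1) {
      for (k in which(immob)) { x[k, ] <- x[k, 1]; y[k, ] <- y[k, 1] }
      if (m$D == 0) for (k in mob_idx) { x[k, ] <- x[k, 1]; y[k, ] <- y[k, 1] }
    }
    out[[reg]] <- data.frame(
      id = rep(next_id:(next_id + n - 1L), each = nf),
      frame = rep(seq_len(nf) - 1L, n),
      x_um = as.vector(t(x)), y_um = as.vector(t(y)),
      region = reg,
      true_D = rep(ifelse(immob, 0, m$D), each = nf),
      mobile = rep(!immob, each = nf))
    next_id <- next_id + n
  }
  if (length(out) == 0)
    return(cbind(empty_trajectory_table(),
                 data.frame(region = character(), true_D = numeric(),
                            mobile = logical())))
  do.call(rbind, out)
}
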