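# Pipeline orchestration ---------------------------------------------------

#' Analysis defaults
#'
#' The numeric defaults of every pipeline stage. Acquisition and analysis
#' constants mirror the reference quantum-dot / nanotube workflow: 28 Hz
#' sampling, 4-point MSD fit, 0.6-0.8 s confinement window, 0.005 um^2/s
#' mobility threshold, >10-point (>= 11) trajectory filter, ring factor
#' 1.82, 10-frame sliding window with 3-point fit, 6-point eccentricity
#' window, and 30 nm localization precision.
#'
#' @return Named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    pixel_size_um = 0.160,
    frame_interval_s = 1 / 28,
    n_frames = 60L,
    field_px = 128L,
    psf_sigma_um = 0.130,
    photon_rate = 2000,
    background = 10,
    localization_jitter_um = 0.030,
    detection_scale = 2L,
    threshold_k = 3,
    window_halfwidth_px = 3L,
    max_displacement_um = 0.5,
    max_gap = 0L,
    min_points = 11L,
    fit_points = 4L,
    confinement_window_s = c(0.6, 0.8),
    immobile_threshold = 0.005,
    ring_factor = 1.82,
    out_bound_factor = 2,
    sliding_window = 10L,
    sliding_fit_points = 3L,
    ecc_window = 6L,
    precision_um = 0.030,
    n_per_region = 20L,
    sim_D = 0.045,
    sim_confinement_radius = Inf,
    sim_immobile_probability = 0,
    input = NULL,
    roi = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Parses a YAML file (or takes a list), rejects unknown keys, checks
#' physical units, fills every unset value with the pipeline default and
#' records which values were defaulted. All violations are reported
#' together, not just the first.
#'
#' @param config Path to a YAML file, or a named list (empty list / empty
#'   file = all defaults).
#' @return A validated `run_config` list with attribute `defaulted` (names
#'   of defaulted keys); errors list every violation.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  errors <- character()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  merged <- defaults
  for (k in intersect(names(config), names(defaults)))
    merged[[k]] <- config[[k]]
  pos_keys <- c("pixel_size_um", "frame_interval_s", "n_frames", "field_px",
                "psf_sigma_um", "max_displacement_um", "ring_factor",
                "sliding_window", "ecc_window", "fit_points",
                "sliding_fit_points", "min_points", "out_bound_factor")
  for (k in pos_keys) {
    v <- merged[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      errors <- c(errors, sprintf("`%s` must be a single positive number", k))
  }
  nonneg_keys <- c("photon_rate", "background", "localization_jitter_um",
                   "immobile_threshold", "precision_um", "max_gap",
                   "sim_immobile_probability", "n_per_region")
  for (k in nonneg_keys) {
    v <- merged[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      errors <- c(errors, sprintf("`%s` must be a single non-negative number", k))
  }
  w <- merged$confinement_window_s
  if (!is.numeric(w) || length(w) != 2) {
    errors <- c(errors, "`confinement_window_s` must be two numbers (lo, hi)")
  } else if (w[1] >= w[2]) {
    errors <- c(errors,
                sprintf("`confinement_window_s` is reversed or empty: %g:%g",
                        w[1], w[2]))
  }
  modes <- c("simulate", "localize", "link", "qd", "rheology", "roi",
             "swcnt", "morphometry", "matrix")
  if (!merged$mode %in% modes)
    errors <- c(errors, sprintf("`mode` must be one of %s",
                                paste(modes, collapse = ", ")))
  if (length(errors) > 0)
    stop(paste(c("invalid configuration:", errors), collapse = "\n  "),
         call. = FALSE)
  structure(merged, class = "run_config",
            defaulted = setdiff(names(defaults), names(config)))
}

sim_config_from <- function(cfg) {
  sim_config(seed = cfg$seed, pixel_size = cfg$pixel_size_um,
             frame_interval = cfg$frame_interval_s, n_frames = cfg$n_frames,
             field_size = c(cfg$field_px, cfg$field_px),
             psf_sigma = cfg$psf_sigma_um, photon_rate = cfg$photon_rate,
             background = cfg$background,
             localization_jitter = cfg$localization_jitter_um)
}

#' Run the pipeline
#'
#' Executes one pipeline mode from a validated configuration and writes all
#' stage outputs (CSV/JSON) plus a reproducibility manifest to `out_dir`.
#' Modes: `simulate` (synthetic ground truth + jittered observations),
#' `localize` (+`link`) for movie input, `qd`/`rheology` for per-trajectory
#' rheology and per-ROI summaries, `roi` for density/penetrability,
#' `swcnt` for local maps, `morphometry` for plaque masks, `matrix` for
#' matrix metrics.
#'
#' The manifest records the config snapshot (with defaulted keys marked),
#' package version, seed, input checksums, per-stage record counts and
#' warnings; identical configs and inputs reproduce outputs bit-identically.
#'
#' @param config A `run_config` from [validate_config()] (or a list/path,
#'   validated on the fly).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  counts <- list()
  warns <- character()
  note <- function(...) counts[[length(counts) + 1]] <<- list(...)
  withCallingHandlers({
    if (config$mode == "simulate") {
      scfg <- sim_config_from(config)
      # bounded resampling: a heavy-tailed core-area draw may not fit the
      # configured field
      geom <- NULL
      for (try in 1:50) {
        geom <- tryCatch(sample_plaque_geometry(scfg, core_area_median = 80,
                                                core_area_sigma_log = 0.5),
                         error = function(e) NULL)
        if (!is.null(geom)) break
      }
      if (is.null(geom))
        stop("stage 'simulate': no plaque geometry fits the field; ",
             "increase `field_px`", call. = FALSE)
      motion <- list(
        Out = motion_model(config$sim_D, config$sim_confinement_radius,
                           config$sim_immobile_probability),
        Ring = motion_model(config$sim_D, config$sim_confinement_radius,
                            config$sim_immobile_probability),
        Amyloid = motion_model(config$sim_D / 2,
                               config$sim_confinement_radius,
                               min(1, config$sim_immobile_probability * 2)))
      truth <- simulate_trajectories(geom, motion, scfg,
                                     config$n_per_region)
      utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE)
      obs <- add_observation_jitter(truth, config$localization_jitter_um)
      obs <- data.frame(traj_id = obs$id, obs[, c("frame", "x_um", "y_um",
                                                  "region")])
      write_trajectories_csv(obs, file.path(out_dir, "trajectories.csv"))
      roi <- build_concentric_rois(center = geom$center,
                                   core_radius = geom$core_radius,
                                   ring_factor = config$ring_factor,
                                   out_bound = geom$out_outer_radius)
      write_roi_json(roi, file.path(out_dir, "roi.json"))
      note(stage = "simulate", n_trajectories = length(unique(truth$id)),
           n_rows = nrow(truth))
    } else if (config$mode %in% c("localize", "link")) {
      movie <- read_movie_tiff(config$input,
                               pixel_size = config$pixel_size_um,
                               frame_interval = config$frame_interval_s)
      locs <- localize_movie(movie, config$detection_scale,
                             config$threshold_k, config$window_halfwidth_px)
      write_localizations_csv(locs, file.path(out_dir, "localizations.csv"))
      note(stage = "localize", n_localizations = nrow(locs))
      if (config$mode == "link") {
        traj <- link_trajectories(locs, config$max_displacement_um,
                                  config$max_gap)
        note(stage = "link", n_trajectories = length(unique(traj$traj_id)))
        traj <- filter_trajectories(traj, config$min_points)
        note(stage = "filter",
             n_retained = length(unique(traj$traj_id)))
        write_trajectories_csv(traj, file.path(out_dir, "trajectories.csv"))
      }
    } else if (config$mode %in% c("qd", "rheology")) {
      traj <- read_trajectories_csv(config$input)
      if (!is.null(config$roi)) {
        roi <- read_roi_json(config$roi)
        traj$roi <- assign_region(cbind(traj$x_um, traj$y_um), roi)
      }
      recs <- analyze_trajectories(traj, config$frame_interval_s,
                                   config$fit_points,
                                   config$confinement_window_s,
                                   config$immobile_threshold)
      utils::write.csv(recs, file.path(out_dir, "rheology.csv"),
                       row.names = FALSE)
      grp <- recs$roi %||% recs$region %||% rep("all", nrow(recs))
      grps <- split(recs, grp)
      summ <- do.call(rbind, lapply(names(grps), function(g) {
        s <- grps[[g]]
        mob <- s[s$mobile & !is.na(s$D_inst), ]
        data.frame(roi = g, n = nrow(s),
                   median_D = if (nrow(mob)) median(mob$D_inst) else NA_real_,
                   iqr_D = if (nrow(mob)) stats::IQR(mob$D_inst) else NA_real_,
                   median_confinement = median(s$confinement_um2,
                                               na.rm = TRUE),
                   immobile_fraction = mean(!s$mobile))
      }))
      utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                       row.names = FALSE)
      msd <- compute_msd_ensemble(traj, config$frame_interval_s)
      utils::write.csv(msd, file.path(out_dir, "msd_ensemble.csv"),
                       row.names = FALSE)
      note(stage = "rheology", n_trajectories = nrow(recs),
           n_groups = nrow(summ))
    } else if (config$mode == "roi") {
      traj <- read_trajectories_csv(config$input)
      roi <- read_roi_json(config$roi)
      dens <- localization_density(traj[, c("x_um", "y_um")], roi)
      dens$ratio_out_ring <- penetrability_ratio(dens, "Out/Ring")
      dens$ratio_ring_amyloid <- tryCatch(
        penetrability_ratio(dens, "Ring/Amyloid"),
        warning = function(w) NA_real_)
      utils::write.csv(dens, file.path(out_dir, "density.csv"),
                       row.names = FALSE)
      note(stage = "roi", n_points = nrow(traj))
    } else if (config$mode == "swcnt") {
      traj <- read_trajectories_csv(config$input)
      kept <- exclude_immobile(traj, config$frame_interval_s)
      maps <- lapply(split(kept$trajectories, kept$trajectories$traj_id),
                     function(tr) {
        lm_ <- local_map(tr, config$frame_interval_s, config$sliding_window,
                         config$sliding_fit_points, config$ecc_window,
                         config$precision_um)
        if (nrow(lm_$local_d) == 0) return(NULL)
        data.frame(traj_id = tr$traj_id[1], lm_$local_d,
                   width_nm = if (is.null(lm_$width)) NA_real_
                              else lm_$width$width_nm %||% NA_real_)
      })
      maps <- do.call(rbind, maps[!vapply(maps, is.null, logical(1))])
      utils::write.csv(maps, file.path(out_dir, "local_map.csv"),
                       row.names = FALSE)
      note(stage = "swcnt",
           n_retained = length(unique(kept$trajectories$traj_id)),
           n_excluded = sum(!kept$criteria$retained))
    } else if (config$mode == "morphometry") {
      img <- tiff::readTIFF(config$input, all = FALSE) * 65535
      if (length(dim(img)) == 3) img <- img[, , 1]
      thr <- isodata_threshold(img)
      mask <- (img > thr) * 1
      lab <- label_components(mask > 0)
      morph <- do.call(rbind, lapply(seq_len(lab$n), function(l) {
        comp <- (lab$labels == l) * 1
        if (sum(comp) < 9) return(NULL)
        cbind(plaque_id = l, plaque_morphometry(comp, config$pixel_size_um))
      }))
      utils::write.csv(morph, file.path(out_dir, "morphometry.csv"),
                       row.names = FALSE)
      note(stage = "morphometry", n_plaques = nrow(morph), threshold = thr)
    } else if (config$mode == "matrix") {
      img <- tiff::readTIFF(config$input, all = FALSE) * 65535
      if (length(dim(img)) == 3) img <- img[, , 1]
      metrics <- matrix_metrics(img)
      utils::write.csv(metrics, file.path(out_dir, "matrix_metrics.csv"),
                       row.names = FALSE)
      note(stage = "matrix", n_rois = nrow(metrics))
    }
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  inputs <- c(config$input, config$roi)
  inputs <- inputs[!vapply(inputs, is.null, logical(1))]
  manifest <- list(
    package = "ecsrheomap",
    version = as.character(packageVersion("ecsrheomap")),
    mode = config$mode,
    seed = config$seed,
    config = config[order(names(config))],
    defaulted_keys = sort(attr(config, "defaulted") %||% character()),
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(unlist(inputs))) else list(),
    stage_counts = counts,
    warnings = warns)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
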