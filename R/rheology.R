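# MSD rheology -------------------------------------------------------------

# accept ground-truth tables (`id`) and linked tables (`traj_id`) alike
as_traj_table <- function(x) {
  if (!"traj_id" %in% names(x)) {
    if (!"id" %in% names(x))
      stop("need a `traj_id` (or `id`) column", call. = FALSE)
    x$traj_id <- x$id
  }
  x
}

#' Time-averaged mean squared displacement of one trajectory
#'
#' Computes the time-averaged MSD over all ordered position pairs at each
#' lag (overlapping pairs), the maximal use of short trajectories. Lags with
#' no pair are omitted. Gapped trajectories are handled through their frame
#' indices: the lag is the frame difference times the frame interval.
#'
#' @param trajectory Table with `frame`, `x_um`, `y_um` for a single
#'   trajectory (>= 2 points, strictly increasing frames).
#' @param frame_interval Frame interval (s).
#' @param max_lag Maximum lag in frames; truncated with a warning when it
#'   reaches or exceeds the trajectory span.
#' @return An `msd_curve`: `data.frame(lag_s, msd_um2, n_pairs)` with
#'   strictly increasing lags.
#' @export
compute_msd <- function(trajectory, frame_interval, max_lag = NULL) {
  stopifnot(nrow(trajectory) >= 2, frame_interval > 0)
  fr <- trajectory$frame
  if (any(diff(fr) <= 0)) stop("frames must be strictly increasing",
                               call. = FALSE)
  span <- fr[length(fr)] - fr[1]
  if (is.null(max_lag)) max_lag <- span
  if (max_lag >= span + 1) {
    warning("`max_lag` exceeds trajectory span; truncated")
    max_lag <- span
  }
  x <- trajectory$x_um; y <- trajectory$y_um
  n <- length(x)
  # accumulate squared displacements by frame lag
  sums <- numeric(max_lag); counts <- integer(max_lag)
  for (i in seq_len(n - 1)) {
    dl <- fr[(i + 1):n] - fr[i]
    keep <- dl <= max_lag
    if (!any(keep)) next
    dl <- dl[keep]
    d2 <- (x[(i + 1):n][keep] - x[i])^2 + (y[(i + 1):n][keep] - y[i])^2
    for (k in seq_along(dl)) {
      sums[dl[k]] <- sums[dl[k]] + d2[k]
      counts[dl[k]] <- counts[dl[k]] + 1L
    }
  }
  lags <- which(counts > 0)
  structure(data.frame(lag_s = lags * frame_interval,
                       msd_um2 = sums[lags] / counts[lags],
                       n_pairs = counts[lags]),
            class = c("msd_curve", "data.frame"))
}

#' Ensemble MSD: equal-weight average of per-trajectory MSD curves
#'
#' @param trajectories Table with `traj_id`, `frame`, `x_um`, `y_um`.
#' @inheritParams compute_msd
#' @return An `msd_curve` with `n_pairs` = number of trajectories
#'   contributing to each lag.
#' @export
compute_msd_ensemble <- function(trajectories, frame_interval,
                                 max_lag = NULL) {
  trajectories <- as_traj_table(trajectories)
  ids <- unique(trajectories$traj_id)
  curves <- lapply(ids, function(id) {
    tr <- trajectories[trajectories$traj_id == id, ]
    if (nrow(tr) < 2) return(NULL)
    ml <- max_lag
    span <- max(tr$frame) - min(tr$frame)
    if (!is.null(ml) && ml > span) ml <- span
    compute_msd(tr, frame_interval, ml)
  })
  curves <- curves[!vapply(curves, is.null, logical(1))]
  if (length(curves) == 0) stop("no trajectory with >= 2 points", call. = FALSE)
  all_lags <- sort(unique(unlist(lapply(curves, function(c) c$lag_s))))
  msd <- vapply(all_lags, function(l) {
    vals <- vapply(curves, function(c) {
      i <- match(TRUE, abs(c$lag_s - l) < 1e-12)
      if (is.na(i)) NA_real_ else c$msd_um2[i]
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  n <- vapply(all_lags, function(l) {
    sum(vapply(curves, function(c) any(abs(c$lag_s - l) < 1e-12), logical(1)))
  }, integer(1))
  structure(data.frame(lag_s = all_lags, msd_um2 = msd, n_pairs = n),
            class = c("msd_curve", "data.frame"))
}

#' Instantaneous diffusion coefficient from an MSD curve
#'
#' Ordinary least-squares line with free intercept through the first
#' `n_fit_points` lags of the MSD curve; `D_inst = slope / 4` (2D). The free
#' intercept absorbs the localization-noise offset (4 * dx^2). Negative
#' fitted slopes are floored to 0 and flagged.
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param n_fit_points Number of initial lags fitted (default 4).
#' @return List with `D_inst` (um^2/s, `NA` with `reason` when the curve has
#'   fewer than `n_fit_points` lags), `intercept`, and `floored` (logical).
#' @export
fit_dinst <- function(msd, n_fit_points = 4L) {
  if (nrow(msd) < n_fit_points)
    return(list(D_inst = NA_real_, intercept = NA_real_, floored = FALSE,
                reason = "fewer lags than fit points"))
  d <- msd[seq_len(n_fit_points), ]
  fit <- lm(msd_um2 ~ lag_s, data = d)
  slope <- unname(coef(fit)[2])
  list(D_inst = max(slope / 4, 0), intercept = unname(coef(fit)[1]),
       floored = slope < 0, reason = NA_character_)
}

#' Confinement area: mean MSD over the plateau window
#'
#' The unweighted mean of MSD values whose lag lies in the closed window
#' (default 0.6-0.8 s; at 28 Hz these are frame lags 17-22, 0.607-0.786 s),
#' the proxy for the area a confined particle explores.
#'
#' @param msd An `msd_curve`.
#' @param window Closed lag window in seconds, `c(lo, hi)`.
#' @return Confinement area (um^2), or `NA` when no lag falls in the window.
#' @export
confinement_area <- function(msd, window = ECS_CONFINEMENT_WINDOW) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  sel <- msd$lag_s >= window[1] & msd$lag_s <= window[2]
  if (!any(sel)) return(NA_real_)
  mean(msd$msd_um2[sel])
}

#' Mobility classification
#'
#' A trajectory is immobile iff its instantaneous diffusion coefficient is
#' strictly lower than the threshold (default 0.005 um^2/s); D exactly at
#' the threshold is mobile.
#'
#' @param D_inst Instantaneous diffusion coefficient(s), um^2/s (>= 0).
#' @param threshold Mobility threshold (um^2/s).
#' @return Character vector `"mobile"` / `"immobile"`.
#' @export
classify_mobility <- function(D_inst, threshold = ECS_IMMOBILE_THRESHOLD) {
  stopifnot(all(D_inst >= 0, na.rm = TRUE))
  ifelse(D_inst < threshold, "immobile", "mobile")
}

#' Immobile fraction per field of view and ROI
#'
#' For each field of view (FOV) and ROI, the fraction of trajectories with
#' D_inst below the mobility threshold. FOV inclusion rule: when the
#' analysis involves plaque compartments, only FOVs whose Amyloid ROI
#' contains at least one immobile trajectory are retained (entire FOVs are
#' dropped from all ROI fractions otherwise). FOVs with no Amyloid-labeled
#' records at all (e.g. plaque-free WT fields) are unaffected by the rule.
#'
#' @param records Table with columns `fov`, `roi`, and either `mobile`
#'   (logical) or `D_inst` (classified with [classify_mobility()]).
#' @param threshold Mobility threshold (um^2/s).
#' @return `data.frame(fov, roi, n_immobile, n_total, fraction)`; ROIs
#'   absent from a FOV yield no row (missing value semantics).
#' @export
immobile_fraction <- function(records, threshold = ECS_IMMOBILE_THRESHOLD) {
  stopifnot(all(c("fov", "roi") %in% names(records)))
  if (!"mobile" %in% names(records)) {
    stopifnot("D_inst" %in% names(records))
    records$mobile <- classify_mobility(records$D_inst, threshold) == "mobile"
  }
  keep_fov <- vapply(split(records, records$fov), function(s) {
    amy <- s[s$roi == "Amyloid", ]
    nrow(amy) == 0 || any(!amy$mobile)
  }, logical(1))
  records <- records[records$fov %in% names(keep_fov)[keep_fov], ]
  if (nrow(records) == 0)
    return(data.frame(fov = character(), roi = character(),
                      n_immobile = integer(), n_total = integer(),
                      fraction = numeric()))
  agg <- do.call(rbind, lapply(split(records,
                                     list(records$fov, records$roi),
                                     drop = TRUE), function(s)
    data.frame(fov = s$fov[1], roi = s$roi[1],
               n_immobile = sum(!s$mobile), n_total = nrow(s),
               fraction = mean(!s$mobile))))
  rownames(agg) <- NULL
  agg[order(agg$fov, agg$roi), ]
}

#' Paired relative change between adjacent compartments
#'
#' Average percentage variation between an outer and an inner compartment
#' value measured in the same field of view:
#' `100 * (x - y) / (0.5 * (x + y))`, with `x` the outermost and `y` the
#' innermost value. With this ordering a *lower* inner value gives a
#' *positive* change; pass `order = "inner_minus_outer"` for the opposite
#' sign convention (both are exposed because published summaries are
#' ambiguous about the sign). Antisymmetric under swapping x and y, and
#' bounded in (-200, 200) for positive inputs.
#'
#' @param x Outer-compartment value(s).
#' @param y Inner-compartment value(s).
#' @param order `"outer_minus_inner"` (default) or `"inner_minus_outer"`.
#' @return Percent change; `NA` where `x + y == 0`.
#' @export
relative_change <- function(x, y, order = c("outer_minus_inner",
                                            "inner_minus_outer")) {
  order <- match.arg(order)
  num <- if (order == "outer_minus_inner") x - y else y - x
  out <- 100 * num / (0.5 * (x + y))
  out[x + y == 0] <- NA_real_
  out
}

#' Per-trajectory rheology records
#'
#' Runs the MSD pipeline on every trajectory of a linked table: 4-point
#' D_inst fit, plateau-window confinement area (reported only when the
#' trajectory spans at least the window upper bound), and mobility class.
#'
#' @param trajectories Table with `traj_id`, `frame`, `x_um`, `y_um` and
#'   optionally `roi` / `fov` columns (carried through).
#' @param frame_interval Frame interval (s).
#' @param n_fit_points Lags in the D_inst fit (default 4).
#' @param window Confinement window (s).
#' @param threshold Mobility threshold (um^2/s).
#' @return `data.frame(traj_id, n_points, D_inst, confinement_um2, mobile,
#'   floored[, roi, fov])`.
#' @export
analyze_trajectories <- function(trajectories, frame_interval,
                                 n_fit_points = 4L,
                                 window = ECS_CONFINEMENT_WINDOW,
                                 threshold = ECS_IMMOBILE_THRESHOLD) {
  trajectories <- as_traj_table(trajectories)
  ids <- unique(trajectories$traj_id)
  out <- lapply(ids, function(id) {
    tr <- trajectories[trajectories$traj_id == id, ]
    msd <- compute_msd(tr, frame_interval)
    fit <- fit_dinst(msd, n_fit_points)
    span_s <- (max(tr$frame) - min(tr$frame)) * frame_interval
    conf <- if (span_s >= window[2]) confinement_area(msd, window) else NA_real_
    rec <- data.frame(traj_id = id, n_points = nrow(tr),
                      D_inst = fit$D_inst, confinement_um2 = conf,
                      mobile = !is.na(fit$D_inst) &&
                        classify_mobility(fit$D_inst, threshold) == "mobile",
                      floored = fit$floored)
    for (col in intersect(c("roi", "fov", "region"), names(tr)))
      rec[[col]] <- tr[[col]][1]
    rec
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
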