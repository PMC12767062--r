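# Trajectory linking -------------------------------------------------------

# Exact rectangular assignment (Jonker-Volgenant style shortest augmenting
# paths with potentials). cost: n x m matrix, n <= m, finite entries.
# Returns, for each row, the assigned column index.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n)
  v <- numeric(m + 1)          # index 1 = virtual column
  p <- integer(m + 1)          # row assigned to each column (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      js <- which(!used)
      js <- js[js > 1L]
      if (length(js) == 0) stop("assignment infeasible", call. = FALSE)
      cur <- cost[i0, js - 1L] - u[i0] - v[js]
      upd <- cur < minv[js]
      minv[js[upd]] <- cur[upd]
      way[js[upd]] <- j0
      j1 <- js[which.min(minv[js])]
      delta <- minv[j1]
      sel <- which(used)
      rows <- p[sel]
      u[rows[rows > 0]] <- u[rows[rows > 0]] + delta
      v[sel] <- v[sel] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match <- integer(n)
  for (j in 2:(m + 1)) if (p[j] > 0) match[p[j]] <- j - 1L
  match
}

# cost of linking two point sets subject to max displacement; unmatched
# endpoints cost `unmatched` each. Returns for each row of `a` the matched
# row of `b` (NA when unmatched). Globally optimal (max cardinality, then
# min total squared displacement, by construction of the costs).
match_points <- function(a, b, max_disp) {
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  U <- max_disp^2
  BIG <- (max(d2) + U + 1) * 4 * (n1 + n2)
  cost <- matrix(BIG, n1 + n2, n1 + n2)
  cd <- d2
  cd[cd > U] <- BIG
  cost[seq_len(n1), seq_len(n2)] <- cd
  cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- U
  cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- U
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  m <- solve_assignment(cost)
  link <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- m[i]
    if (j <= n2 && d2[i, j] <= U) link[i] <- j
  }
  link
}

#' Link localizations into trajectories
#'
#' Frame-to-frame linking by globally optimal assignment: between each pair
#' of consecutive frames the total squared displacement is minimized subject
#' to a maximum displacement, with unmatched points allowed (track ends /
#' births) at the standard cost of the squared search radius. This is the
#' deterministic equivalent of stochastic (annealing-based) reconnection
#' used by single-molecule tracking software. Optional gap closing joins a
#' track end to a later track start across up to `max_gap` missing frames.
#'
#' @param localizations `data.frame` with `frame` (integer), `x_um`, `y_um`,
#'   sorted by frame (any extra columns are carried through).
#' @param max_displacement Maximum frame-to-frame displacement (um).
#' @param max_gap Maximum number of missing frames bridged by gap closing
#'   (default 0: no gaps).
#' @return Trajectory table: the input rows plus a `traj_id` column, sorted
#'   by `traj_id` then `frame`. Unlinkable points become single-point
#'   trajectories (filter with [filter_trajectories()]).
#' @export
link_trajectories <- function(localizations, max_displacement, max_gap = 0L) {
  stopifnot(max_displacement > 0, max_gap >= 0)
  loc <- localizations
  if (nrow(loc) == 0) {
    loc$traj_id <- integer(0)
    return(loc)
  }
  if (is.unsorted(loc$frame)) stop("localizations must be sorted by frame",
                                   call. = FALSE)
  loc$.row <- seq_len(nrow(loc))
  tid <- integer(nrow(loc))
  frames <- sort(unique(loc$frame))
  by_frame <- split(loc, loc$frame)
  first <- by_frame[[as.character(frames[1])]]
  tid[first$.row] <- seq_len(nrow(first))
  next_id <- nrow(first) + 1L
  for (k in seq_along(frames)[-1]) {
    prev <- by_frame[[as.character(frames[k - 1])]]
    cur <- by_frame[[as.character(frames[k])]]
    link <- if (frames[k] - frames[k - 1] == 1L)
      match_points(cbind(prev$x_um, prev$y_um),
                   cbind(cur$x_um, cur$y_um), max_displacement)
    else rep(NA_integer_, nrow(prev))
    taken <- rep(FALSE, nrow(cur))
    for (i in seq_len(nrow(prev))) {
      if (!is.na(link[i])) {
        tid[cur$.row[link[i]]] <- tid[prev$.row[i]]
        taken[link[i]] <- TRUE
      }
    }
    for (j in which(!taken)) {
      tid[cur$.row[j]] <- next_id
      next_id <- next_id + 1L
    }
  }
  loc$traj_id <- tid
  if (max_gap >= 1) loc <- close_gaps(loc, max_displacement, max_gap)
  loc <- loc[order(loc$traj_id, loc$frame), ]
  # renumber densely in (first frame, id) order for determinism
  first_frame <- tapply(loc$frame, loc$traj_id, min)
  ord <- order(first_frame, as.integer(names(first_frame)))
  remap <- setNames(seq_along(ord), names(first_frame)[ord])
  loc$traj_id <- as.integer(remap[as.character(loc$traj_id)])
  loc <- loc[order(loc$traj_id, loc$frame), ]
  rownames(loc) <- NULL
  loc$.row <- NULL
  loc[, c("traj_id", setdiff(names(loc), "traj_id"))]
}

# join track ends to later track starts (gap 1..max_gap frames), optimal
# assignment per pass, repeated until no merge occurs
close_gaps <- function(loc, max_displacement, max_gap) {
  repeat {
    ids <- unique(loc$traj_id)
    info <- do.call(rbind, lapply(ids, function(id) {
      s <- loc[loc$traj_id == id, ]
      data.frame(id = id,
                 f0 = s$frame[1], x0 = s$x_um[1], y0 = s$y_um[1],
                 f1 = s$frame[nrow(s)], x1 = s$x_um[nrow(s)],
                 y1 = s$y_um[nrow(s)])
    }))
    pairs <- expand.grid(e = seq_len(nrow(info)), s = seq_len(nrow(info)))
    gap <- info$f0[pairs$s] - info$f1[pairs$e]
    d <- sqrt((info$x0[pairs$s] - info$x1[pairs$e])^2 +
                (info$y0[pairs$s] - info$y1[pairs$e])^2)
    ok <- gap >= 2 & gap <= max_gap + 1 & d <= max_displacement
    if (!any(ok)) return(loc)
    ends <- unique(pairs$e[ok]); starts <- unique(pairs$s[ok])
    d2 <- matrix(Inf, length(ends), length(starts))
    for (r in which(ok)) {
      d2[match(pairs$e[r], ends), match(pairs$s[r], starts)] <- d[r]^2
    }
    U <- max_displacement^2
    d2[!is.finite(d2)] <- (U + 1) * 4 * (length(ends) + length(starts))
    link <- match_points_cost(d2, U)
    merged <- FALSE
    for (i in seq_along(ends)) {
      j <- link[i]
      if (is.na(j)) next
      loc$traj_id[loc$traj_id == info$id[starts[j]]] <- info$id[ends[i]]
      merged <- TRUE
    }
    if (!merged) return(loc)
  }
}

# assignment on a prebuilt cost matrix with unmatched cost U
match_points_cost <- function(d2, U) {
  n1 <- nrow(d2); n2 <- ncol(d2)
  BIG <- max(d2, U) * 4 * (n1 + n2) + 1
  cost <- matrix(BIG, n1 + n2, n1 + n2)
  cd <- d2; cd[cd > U] <- BIG
  cost[seq_len(n1), seq_len(n2)] <- cd
  cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- U
  cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- U
  cost[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  m <- solve_assignment(cost)
  link <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) if (m[i] <= n2 && d2[i, m[i]] <= U) link[i] <- m[i]
  link
}

#' Filter trajectories by minimum length
#'
#' Retains trajectories with at least `min_points` localizations. The
#' default 11 reads the "more than 10 points" rule strictly
#' (> 10, i.e. >= 11).
#'
#' @param trajectories Table with a `traj_id` column.
#' @param min_points Minimum number of points (>= 2).
#' @return The filtered table.
#' @export
filter_trajectories <- function(trajectories, min_points = 11L) {
  if (min_points < 2) stop("`min_points` must be >= 2", call. = FALSE)
  if (nrow(trajectories) == 0) return(trajectories)
  counts <- table(trajectories$traj_id)
  keep <- names(counts)[counts >= min_points]
  out <- trajectories[trajectories$traj_id %in% as.integer(keep) |
                        trajectories$traj_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
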