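# Independent oracles and small fixture builders used across tests.

# O(n^2) brute-force time-averaged MSD (double loop over ordered pairs)
msd_bruteforce <- function(traj, frame_interval) {
  n <- nrow(traj)
  sums <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      lag <- traj$frame[j] - traj$frame[i]
      d2 <- (traj$x_um[j] - traj$x_um[i])^2 + (traj$y_um[j] - traj$y_um[i])^2
      key <- as.character(lag)
      sums[[key]] <- c(sums[[key]], d2)
    }
  }
  lags <- sort(as.integer(names(sums)))
  data.frame(lag_s = lags * frame_interval,
             msd_um2 = vapply(as.character(lags),
                              function(k) mean(sums[[k]]), numeric(1)),
             n_pairs = vapply(as.character(lags),
                              function(k) length(sums[[k]]), numeric(1)))
}

# exhaustive frame-pair matching oracle: minimal total cost where each link
# costs its squared displacement (if <= max_disp) and each unmatched
# endpoint costs max_disp^2 (same objective as the linker)
all_matchings <- function(n1, n2) {
  # list of integer vectors length n1 with values in 0 (unmatched) or 1..n2,
  # nonzero values distinct
  res <- list()
  rec <- function(i, used, cur) {
    if (i > n1) { res[[length(res) + 1]] <<- cur; return(invisible()) }
    rec(i + 1, used, c(cur, 0L))
    for (j in seq_len(n2)) if (!(j %in% used))
      rec(i + 1, c(used, j), c(cur, j))
  }
  rec(1L, integer(), integer())
  res
}

linking_cost_oracle <- function(a, b, max_disp) {
  n1 <- nrow(a); n2 <- nrow(b)
  U <- max_disp^2
  if (n1 == 0 || n2 == 0) return((n1 + n2) * U)
  best <- Inf
  for (m in all_matchings(n1, n2)) {
    cost <- 0
    ok <- TRUE
    for (i in seq_len(n1)) {
      j <- m[i]
      if (j == 0) { cost <- cost + U; next }
      d2 <- sum((a[i, ] - b[j, ])^2)
      if (d2 > U) { ok <- FALSE; break }
      cost <- cost + d2
    }
    if (!ok) next
    cost <- cost + sum(!(seq_len(n2) %in% m)) * U
    best <- min(best, cost)
  }
  best
}

# total cost of a linked result under the same objective
linking_cost_of <- function(linked, frames, max_disp) {
  U <- max_disp^2
  total <- 0
  for (k in seq_along(frames)[-1]) {
    a <- linked[linked$frame == frames[k - 1], ]
    b <- linked[linked$frame == frames[k], ]
    shared <- intersect(a$traj_id, b$traj_id)
    for (id in shared) {
      d2 <- (a$x_um[a$traj_id == id] - b$x_um[b$traj_id == id])^2 +
        (a$y_um[a$traj_id == id] - b$y_um[b$traj_id == id])^2
      total <- total + d2
    }
    total <- total + (nrow(a) - length(shared)) * U +
      (nrow(b) - length(shared)) * U
  }
  total
}

# rasterized filled disk mask
disk_mask <- function(radius_px, pad = 10) {
  n <- 2 * (radius_px + pad) + 1
  ctr <- radius_px + pad + 1
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((rows - ctr)^2 + (cols - ctr)^2 <= radius_px^2) * 1
}

# Sierpinski carpet raster (3^depth pixels per side)
sierpinski_carpet <- function(depth) {
  m <- matrix(1, 3^depth, 3^depth)
  for (lev in seq_len(depth)) {
    s <- 3^(lev - 1)
    blocks <- 3^depth / 3^lev
    for (r in 0:(blocks - 1)) for (c in 0:(blocks - 1)) {
      m[(r * 3^lev + s + 1):(r * 3^lev + 2 * s),
        (c * 3^lev + s + 1):(c * 3^lev + 2 * s)] <- 0
    }
  }
  m
}

# Monte-Carlo oracle for E|P1 - P2|^2 of independent uniform points in a disk
disk_pairdist2_mc <- function(R, n = 2e5) {
  th <- runif(2 * n, 0, 2 * pi)
  r <- R * sqrt(runif(2 * n))
  x <- r * cos(th); y <- r * sin(th)
  mean((x[1:n] - x[(n + 1):(2 * n)])^2 + (y[1:n] - y[(n + 1):(2 * n)])^2)
}
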