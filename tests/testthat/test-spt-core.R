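# Detection, localization, linking, filtering, precision.

test_that("rolling-average preprocessing behaves like a truncated mean", {
  cfg <- sim_config(seed = 1, field_size = c(8, 8), n_frames = 5,
                    background = 0)
  frames <- array(0, c(8, 8, 5))
  frames[4, 4, 3] <- 9  # impulse in the middle frame
  mov <- spt_movie(frames, cfg$pixel_size, cfg$frame_interval)

  expect_identical(preprocess_movie(mov, 1)$frames, frames)

  const <- spt_movie(array(7, c(8, 8, 5)), 0.16, 1 / 28)
  expect_equal(preprocess_movie(const, 3)$frames, const$frames)

  sm <- preprocess_movie(mov, 3)
  expect_equal(sm$frames[4, 4, 2:4], rep(3, 3))
  expect_equal(sm$frames[4, 4, c(1, 5)], c(0, 0))

  expect_error(preprocess_movie(mov, 7), "exceeds")
  expect_error(preprocess_movie(mov, 2), "odd")
})

test_that("wavelet detection finds rendered spots and nothing on blanks", {
  expect_equal(nrow(detect_spots(matrix(5, 64, 64))), 0)

  cfg <- sim_config(seed = 3, field_size = c(64, 64), n_frames = 1,
                    photon_rate = 5000, background = 10)
  tr <- data.frame(id = 1:2, frame = 0, x_um = c(3.0, 4.6), y_um = c(3.0, 3.0))
  set.seed(3)
  mov <- render_movie(tr, cfg)  # two emitters 10 px apart
  cand <- detect_spots(mov$frames[, , 1], threshold_k = 5)
  expect_equal(nrow(cand), 2)
  got <- sort(cand$col)
  expect_true(all(abs(got - 1 - c(3.0, 4.6) / 0.16) <= 1))
  expect_true(all(abs(cand$row - 1 - 3.0 / 0.16) <= 1))

  expect_equal(nrow(detect_spots(mov$frames[, , 1], threshold_k = 1e9)), 0)
})

test_that("Gaussian fitting recovers sub-pixel centers", {
  px <- matrix(rep(0:20, each = 21), 21, 21)
  py <- matrix(rep(0:20, times = 21), 21, 21)
  img <- 5 + 100 * exp(-((px - 10.30)^2 + (py - 15.70)^2) / (2 * 1.3^2))
  f <- fit_gaussian(img, list(row = 17, col = 11), 3, 1)
  expect_true(f$converged)
  expect_lt(abs(f$x_um - 10.30), 0.02)
  expect_lt(abs(f$y_um - 15.70), 0.02)

  # candidate at the border: truncated window, still flagged
  fb <- fit_gaussian(img, list(row = 2, col = 2), 3, 1)
  expect_true(fb$truncated)

  # flat window cannot converge
  ff <- fit_gaussian(matrix(3, 15, 15), list(row = 8, col = 8), 3, 1)
  expect_false(ff$converged)
})

test_that("detection recall and localization error meet the SNR-10 bar", {
  set.seed(9)
  gx <- as.vector(outer(seq(1.5, 8.5, 1.4), rep(1, 6)))
  gy <- as.vector(outer(rep(1, 6), seq(1.5, 8.5, 1.4)))
  pos <- cbind(gx, gy) + matrix(runif(2 * length(gx), -0.3, 0.3), ncol = 2)
  n <- nrow(pos)
  cfg <- sim_config(seed = 9, field_size = c(64, 64), n_frames = 1,
                    photon_rate = 3000, background = 10)
  mov <- render_movie(data.frame(id = seq_len(n), frame = 0,
                                 x_um = pos[, 1], y_um = pos[, 2]), cfg)
  locs <- localize_movie(mov)
  err <- vapply(seq_len(n), function(i)
    min(sqrt((locs$x_um - pos[i, 1])^2 + (locs$y_um - pos[i, 2])^2)),
    numeric(1))
  matched <- err <= cfg$pixel_size  # ground truth matched within 1 px
  expect_gte(mean(matched), 0.95)
  rmse_px <- sqrt(mean(err[matched]^2)) / cfg$pixel_size
  expect_lte(rmse_px, 0.25)
})

test_that("linking matches the exhaustive assignment oracle", {
  set.seed(20)
  max_disp <- 1.0
  for (trial in 1:12) {
    n_particles <- sample(2:4, 1)
    n_frames <- 5
    # random walks with occasional detection dropouts
    rows <- list()
    for (p in seq_len(n_particles)) {
      x <- cumsum(c(runif(1, 0, 5), rnorm(n_frames - 1, 0, 0.25)))
      y <- cumsum(c(runif(1, 0, 5), rnorm(n_frames - 1, 0, 0.25)))
      keep <- runif(n_frames) > 0.15
      rows[[p]] <- data.frame(frame = (0:(n_frames - 1))[keep],
                              x_um = x[keep], y_um = y[keep])
    }
    locs <- do.call(rbind, rows)
    locs <- locs[order(locs$frame), ]
    if (nrow(locs) < 2) next
    linked <- link_trajectories(locs, max_disp)
    frames <- sort(unique(locs$frame))
    oracle <- 0
    for (k in seq_along(frames)[-1]) {
      if (frames[k] - frames[k - 1] != 1) {
        a <- locs[locs$frame == frames[k - 1], c("x_um", "y_um")]
        b <- locs[locs$frame == frames[k], c("x_um", "y_um")]
        oracle <- oracle + (nrow(a) + nrow(b)) * max_disp^2
        next
      }
      a <- as.matrix(locs[locs$frame == frames[k - 1], c("x_um", "y_um")])
      b <- as.matrix(locs[locs$frame == frames[k], c("x_um", "y_um")])
      oracle <- oracle + linking_cost_oracle(a, b, max_disp)
    }
    expect_equal(linking_cost_of(linked, frames, max_disp), oracle,
                 tolerance = 1e-9)
  }
})

test_that("well-separated particles yield clean disjoint trajectories", {
  locs <- data.frame(frame = rep(0:4, each = 2),
                     x_um = c(rbind(seq(0, 0.4, 0.1), seq(10, 10.4, 0.1))),
                     y_um = 0)
  linked <- link_trajectories(locs, max_displacement = 2)
  expect_equal(length(unique(linked$traj_id)), 2)
  expect_true(all(table(linked$traj_id) == 5))
  # disjointness: every localization used exactly once
  expect_equal(nrow(linked), nrow(locs))
  expect_false(any(duplicated(linked[, c("traj_id", "frame")])))

  # one missing frame with max_gap 1 spans the gap
  gap <- data.frame(frame = c(0, 1, 3, 4), x_um = c(0, 0.1, 0.3, 0.4),
                    y_um = 0)
  expect_equal(length(unique(link_trajectories(gap, 0.5, max_gap = 1)$traj_id)),
               1)
  expect_equal(length(unique(link_trajectories(gap, 0.5, max_gap = 0)$traj_id)),
               2)
})

test_that("trajectory filter keeps only >10-point tracks by default", {
  lens <- c(5, 10, 11, 40)
  tab <- do.call(rbind, lapply(seq_along(lens), function(i)
    data.frame(traj_id = i, frame = seq_len(lens[i]) - 1, x_um = 0,
               y_um = 0)))
  kept <- filter_trajectories(tab)
  expect_setequal(unique(table(kept$traj_id)), c(11, 40))

  expect_equal(nrow(filter_trajectories(tab[0, ])), 0)
  expect_equal(nrow(filter_trajectories(tab, min_points = 2)), nrow(tab))
  expect_error(filter_trajectories(tab, min_points = 1), ">= 2")
})

test_that("precision estimation is unbiased on simulated jitter", {
  expect_equal(estimate_precision(
    data.frame(frame = 0:49, x_um = 1, y_um = 2), 1 / 28)$sigma_mean, 0)

  # only emitters that pass the immobility precondition enter the
  # precision analysis (at 28 Hz a 60 nm jitter is occasionally
  # indistinguishable from slow motion; such emitters are rejected)
  set.seed(33)
  for (sigma in c(0.010, 0.030, 0.060)) {
    est <- replicate(40, {
      tr <- data.frame(frame = 0:49,
                       x_um = 3 + rnorm(50, 0, sigma),
                       y_um = 3 + rnorm(50, 0, sigma))
      tryCatch(estimate_precision(tr, 1 / 28)$sigma_mean,
               error = function(e) NA_real_)
    })
    expect_gte(sum(!is.na(est)), 20)  # majority classify immobile
    expect_lt(abs(mean(est, na.rm = TRUE) - sigma) / sigma, 0.15)
  }

  # a mobile trajectory is rejected
  set.seed(34)
  mob <- simulate_free_trajectories(1, 0.05, 50, 1 / 28)
  expect_error(estimate_precision(mob, 1 / 28), "mobile")

  # the 30 nm precision feeds the error model: ~0.01 um^2/s
  expect_equal(dinst_error(0.030, 3, 0.030), 0.01)
})
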