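# Nanotube local analysis: drift, sliding D, eccentricity, local width.

test_that("drift correction removes injected linear drift", {
  set.seed(60)
  n_frames <- 60
  drift <- 0.005 * (0:(n_frames - 1))  # 5 nm/frame
  ref <- data.frame(traj_id = 1, frame = 0:(n_frames - 1),
                    x_um = 2 + drift + rnorm(n_frames, 0, 1e-4),
                    y_um = 2 + rnorm(n_frames, 0, 1e-4))
  mob <- simulate_free_trajectories(1, 0.04, n_frames, 0.033)
  mob$x_um <- mob$x_um + drift
  tr <- rbind(ref, data.frame(traj_id = 2, frame = mob$frame,
                              x_um = mob$x_um, y_um = mob$y_um))
  fixed <- correct_drift(tr, reference_ids = 1)
  res <- fixed[fixed$traj_id == 2, ]
  residual <- diff(res$x_um - (mob$x_um - drift))
  expect_lt(max(abs(residual)), 0.001)  # < 1 nm/frame

  expect_warning(correct_drift(tr, reference_ids = integer()), "no immobile")
  # identical references equal the single-reference correction
  tr3 <- rbind(tr, transform(ref, traj_id = 3))
  expect_equal(correct_drift(tr3, c(1, 3))[1:nrow(tr), c("x_um", "y_um")],
               correct_drift(tr, 1)[, c("x_um", "y_um")])
})

test_that("sliding D_inst maps homogeneous and piecewise diffusivity", {
  static <- data.frame(frame = 0:29, x_um = 1, y_um = 1)
  expect_true(all(sliding_dinst(static, 0.033)$local_D == 0))
  expect_equal(nrow(sliding_dinst(static[1:5, ], 0.033)), 0)

  set.seed(61)
  tr <- simulate_free_trajectories(60, 0.038, 200, 0.033)
  ld <- unlist(lapply(split(tr, tr$id), function(s)
    sliding_dinst(s, 0.033)$local_D))
  expect_equal(median(ld), 0.038, tolerance = 0.15)
  # spatial map of homogeneous diffusion has no positional trend
  one <- sliding_dinst(tr[tr$id == 1, ], 0.033)
  fit <- lm(local_D ~ x_um, data = one)
  expect_gt(summary(fit)$coefficients[2, 4], 0.01)  # slope consistent with 0

  # piecewise D = 0.02 then 0.10: window medians differ ~5x between halves
  set.seed(62)
  lo <- simulate_free_trajectories(20, 0.02, 100, 0.033)
  hi <- simulate_free_trajectories(20, 0.10, 100, 0.033)
  ratio <- median(unlist(lapply(split(hi, hi$id), function(s)
    sliding_dinst(s, 0.033)$local_D))) /
    median(unlist(lapply(split(lo, lo$id), function(s)
      sliding_dinst(s, 0.033)$local_D)))
  expect_equal(ratio, 5, tolerance = 0.25)
})

test_that("immobile nanotubes are excluded by their plateau-shaped MSD", {
  set.seed(63)
  jitter_only <- data.frame(id = 1, frame = 0:59,
                            x_um = 1 + rnorm(60, 0, 0.03),
                            y_um = 1 + rnorm(60, 0, 0.03))
  free <- simulate_free_trajectories(1, 0.04, 60, 0.033)
  free$id <- 2
  res <- exclude_immobile(rbind(jitter_only, free), 0.033)
  expect_identical(unique(res$trajectories$traj_id), 2)
  expect_named(res$criteria, c("traj_id", "plateau_ratio", "D_inst",
                               "retained"))
})

test_that("window eccentricity reflects the covariance axis ratio", {
  set.seed(64)
  # isotropic cloud: eccentricity near 1 (one big window)
  iso <- data.frame(x_um = rnorm(400, 0, 0.5), y_um = rnorm(400, 0, 0.5))
  e_iso <- window_eccentricity(iso, window = 400, precision = 0.001)
  expect_equal(e_iso$eccentricity, 1, tolerance = 0.15)

  # 2:1 axis-aligned cloud converges to 2
  aniso <- data.frame(x_um = rnorm(2000, 0, 1), y_um = rnorm(2000, 0, 0.5))
  e2 <- window_eccentricity(aniso, window = 2000, precision = 0.001)
  expect_equal(e2$eccentricity, 2, tolerance = 0.1)

  # rotation invariance
  th <- 0.7
  rot <- data.frame(x_um = cos(th) * aniso$x_um - sin(th) * aniso$y_um,
                    y_um = sin(th) * aniso$x_um + cos(th) * aniso$y_um)
  er <- window_eccentricity(rot, window = 2000, precision = 0.001)
  expect_equal(er$eccentricity, e2$eccentricity, tolerance = 1e-9)

  # collinear window flags an infinite-eccentricity sentinel
  line <- data.frame(x_um = seq(0, 1, length.out = 6), y_um = 0)
  el <- window_eccentricity(line, window = 6, precision = 0)
  expect_true(el$collinear)
  expect_identical(el$eccentricity, Inf)
  # with noise the same line is large but finite
  line2 <- line; line2$y_um <- rnorm(6, 0, 1e-4)
  expect_gt(window_eccentricity(line2, 6, 1e-5)$eccentricity, 10)
})

test_that("maximum-confinement selection takes the earliest maximum", {
  ecc <- data.frame(window_index = 1:4, eccentricity = c(1, 3, 2, 3),
                    sigma_minor2 = 1, collinear = FALSE)
  expect_equal(select_max_confinement(ecc), 2)  # tie -> earliest
  one <- ecc[1, ]
  expect_equal(select_max_confinement(one), 1)
  mono <- ecc; mono$eccentricity <- 1:4
  expect_equal(select_max_confinement(mono), 4)
  flagged <- ecc; flagged$collinear <- TRUE
  expect_true(is.na(select_max_confinement(flagged)))
})

test_that("local width follows the uniform-occupancy model", {
  set.seed(65)
  # noise-free points uniform across a 100 nm channel, large n -> 100 nm
  pos <- data.frame(x_um = seq(0, 10, length.out = 5000),
                    y_um = runif(5000, -0.05, 0.05))
  w <- estimate_local_width(pos, precision = 0, calibration = 1)
  expect_equal(w$width_nm, 100, tolerance = 0.05)

  # precision equal to the observed spread flags below-resolution
  flat <- data.frame(x_um = seq(0, 1, length.out = 50),
                     y_um = rnorm(50, 0, 0.02))
  sm <- sqrt(min(eigen(cov(cbind(flat$x_um, flat$y_um)))$values))
  wb <- estimate_local_width(flat, precision = sm * 1.01)
  expect_true(wb$below_resolution)
  expect_true(is.na(wb$width_nm))
})

test_that("channel width recovery holds across 60-140 nm with the stored calibration", {
  widths <- c(60, 78, 100, 140)
  for (i in seq_along(widths)) {
    set.seed(70 + i)
    tr <- simulate_channel_trajectories(120, 0.04, widths[i] / 1000, 100,
                                        0.033)
    tr <- add_observation_jitter(tr, 0.030)
    est <- vapply(split(tr, tr$id), function(s) {
      lm_ <- local_map(s, 0.033)
      if (is.null(lm_$width) || lm_$width$below_resolution) 0
      else lm_$width$width_nm
    }, numeric(1))
    expect_equal(median(est), widths[i], tolerance = 0.20)
  }
})

test_that("the D_inst error model is exact", {
  expect_identical(dinst_error(0.030, 3, 0.030), 0.030^2 / 0.090)
  expect_equal(dinst_error(0.030, 3, 0.030), 0.01)
  expect_equal(dinst_error(0.060), 4 * dinst_error(0.030))
  expect_equal(dinst_error(0), 0)
  expect_error(dinst_error(0.03, 3, 0), "> 0")
})
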