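# Synthetic-data generator: geometry, motion, rendering, masks.

test_that("plaque geometry derives radii from log-normal core areas", {
  cfg <- sim_config(seed = 1, field_size = c(512, 512))
  set.seed(1)
  g <- sample_plaque_geometry(cfg, core_area_median = 134.2,
                              core_area_sigma_log = 0)
  expect_equal(g$core_radius, sqrt(134.2 / pi), tolerance = 1e-10)
  expect_equal(g$ring_outer_radius, g$core_radius * 2.82, tolerance = 1e-10)

  # construction guarantees log-normality of sampled core areas
  big <- sim_config(seed = 1, field_size = c(2048, 2048))
  set.seed(2)
  areas <- replicate(2000, sample_plaque_geometry(
    big, core_area_median = 50, core_area_sigma_log = 0.8)$core_area)
  expect_true(lognormality_check(areas)$pass)

  # geometry that cannot fit the field errors, naming the radius
  small <- sim_config(seed = 1, field_size = c(64, 64))
  expect_error(
    sample_plaque_geometry(small, core_area_median = 500,
                           core_area_sigma_log = 0),
    "ring_outer_radius")
})

test_that("free diffusion reproduces the 4Dt law within 3 SE", {
  set.seed(10)
  D <- 0.05; dt <- 1 / 28
  tr <- simulate_free_trajectories(1000, D, 10, dt)
  # lag closest to 0.1 s: 3 frames = 0.107 s
  d2 <- vapply(split(tr, tr$id), function(s)
    (s$x_um[4] - s$x_um[1])^2 + (s$y_um[4] - s$y_um[1])^2, numeric(1))
  expected <- 4 * D * 3 * dt
  se <- sd(d2) / sqrt(length(d2))
  expect_lt(abs(mean(d2) - expected), 3 * se)
})

test_that("disk confinement reaches the analytic R^2 plateau", {
  R <- 0.305
  set.seed(11)
  mc <- disk_pairdist2_mc(R)
  expect_equal(mc, R^2, tolerance = 0.02)  # Monte-Carlo oracle = analytic

  set.seed(12)
  tr <- simulate_confined_trajectories(200, 0.15, R, 60, 1 / 28,
                                       substeps = 10)
  msd <- compute_msd_ensemble(tr, 1 / 28)
  plateau <- mean(msd$msd_um2[msd$lag_s >= 0.6 & msd$lag_s <= 0.8])
  expect_equal(plateau, R^2, tolerance = 0.05)
  # no particle ever leaves its domain
  r <- sqrt(tr$x_um^2 + tr$y_um^2)
  expect_true(all(r <= R + 1e-9))
})

test_that("immobile particles and zero-diffusion trajectories are static", {
  set.seed(13)
  tr <- simulate_free_trajectories(5, 0, 20, 1 / 28)
  expect_true(all(tapply(tr$x_um, tr$id, function(x) all(x == x[1]))))

  cfg <- sim_config(seed = 1, field_size = c(256, 256), n_frames = 15)
  g <- sample_plaque_geometry(cfg, 80, 0)
  motion <- list(Out = motion_model(0.05, immobile_probability = 1))
  gt <- simulate_trajectories(g, motion, cfg, 8)
  expect_true(all(tapply(gt$x_um, gt$id, function(x) all(x == x[1]))))
  expect_true(all(!gt$mobile))
})

test_that("region-labeled trajectories never leave their region", {
  cfg <- sim_config(seed = 1, field_size = c(256, 256), n_frames = 40)
  set.seed(14)
  g <- sample_plaque_geometry(cfg, 60, 0)
  motion <- list(Out = motion_model(0.1), Ring = motion_model(0.1),
                 Amyloid = motion_model(0.1))
  gt <- simulate_trajectories(g, motion, cfg, 10, substeps = 10)
  r <- sqrt((gt$x_um - g$center[1])^2 + (gt$y_um - g$center[2])^2)
  eps <- 1e-9
  expect_true(all(r[gt$region == "Amyloid"] <= g$core_radius + eps))
  expect_true(all(r[gt$region == "Ring"] >= g$core_radius - eps &
                    r[gt$region == "Ring"] <= g$ring_outer_radius + eps))
  expect_true(all(r[gt$region == "Out"] >= g$ring_outer_radius - eps &
                    r[gt$region == "Out"] <= g$out_outer_radius + eps))
  # particle count per region conserved across frames
  counts <- table(gt$region, gt$frame)
  expect_true(all(apply(counts, 1, function(x) length(unique(x)) == 1)))
})

test_that("same seed gives bit-identical trajectories and movies", {
  cfg <- sim_config(seed = 5, field_size = c(48, 48), n_frames = 5)
  make <- function() {
    set.seed(cfg$seed)
    tr <- simulate_free_trajectories(3, 0.05, 5, cfg$frame_interval,
                                     origin = c(3.8, 3.8))
    list(tr = tr, mov = render_movie(tr, cfg))
  }
  a <- make(); b <- make()
  expect_identical(a$tr, b$tr)
  expect_identical(a$mov$frames, b$mov$frames)
})

test_that("movie rendering is photometrically sane", {
  cfg <- sim_config(seed = 1, field_size = c(32, 32), n_frames = 3,
                    background = 0)
  empty <- render_movie(empty_traj <- data.frame(id = integer(),
                                                 frame = integer(),
                                                 x_um = numeric(),
                                                 y_um = numeric()),
                        cfg, noise = FALSE)
  expect_true(all(empty$frames == 0))

  tr <- data.frame(id = 1, frame = 0:2, x_um = 2.05, y_um = 1.44)
  mov <- render_movie(tr, cfg, noise = FALSE)
  for (f in 1:3) {
    am <- which(mov$frames[, , f] == max(mov$frames[, , f]), arr.ind = TRUE)
    # pixel centers at integer indices starting 0: x = 2.05 um -> col0 12.8
    expect_equal(unname(am[1, "col"]) - 1, round(2.05 / cfg$pixel_size))
    expect_equal(unname(am[1, "row"]) - 1, round(1.44 / cfg$pixel_size))
  }
  expect_error(render_movie(data.frame(id = 1, frame = 0, x_um = 99,
                                       y_um = 1), cfg),
               "outside the camera field")
})

test_that("TIFF round trip preserves frames and metadata", {
  cfg <- sim_config(seed = 2, field_size = c(24, 24), n_frames = 4)
  set.seed(2)
  tr <- simulate_free_trajectories(2, 0.02, 4, cfg$frame_interval,
                                   origin = c(1.9, 1.9))
  mov <- render_movie(tr, cfg)
  path <- tempfile(fileext = ".tif")
  write_movie_tiff(mov, path, seed = 2)
  back <- read_movie_tiff(path)
  expect_equal(back$pixel_size, cfg$pixel_size)
  expect_equal(back$frame_interval, cfg$frame_interval)
  expect_equal(round(back$frames), round(mov$frames), tolerance = 1)
  unlink(c(path, paste0(path, ".json")))
})

test_that("plaque mask generator hits each requested phenotype class", {
  for (cl in c("compact", "intermediate", "filamentous")) {
    m <- generate_plaque_mask(cl, 256, seed = 21)
    expect_equal(classify_phenotype(circularity(m)), cl)
  }
  # a plain rasterized disk classifies compact
  expect_identical(classify_phenotype(circularity(disk_mask(50))), "compact")
})

test_that("matrix mask generator spans intact / degraded / empty regimes", {
  empty <- generate_matrix_mask("empty", 128)
  expect_equal(percent_area(empty), 0)
  expect_equal(box_count_fractal(empty), 0)

  intact <- generate_matrix_mask("intact", 128, seed = 31)
  expect_gt(percent_area(intact), 20)
  d <- box_count_fractal(skeletonize(intact))
  expect_gt(d, 1.3); expect_lt(d, 1.8)

  degraded <- generate_matrix_mask("degraded", 128, seed = 32)
  expect_lt(percent_area(degraded), percent_area(intact))

  full <- matrix(1, 128, 128)
  expect_equal(box_count_fractal(full), 2, tolerance = 0.05)
})
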