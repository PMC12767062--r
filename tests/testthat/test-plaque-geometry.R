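# Concentric ROIs, penetrability, morphometry, circularity phenotyping.

test_that("circle approximation converts areas to radii and widths", {
  expect_equal(area_to_radius(pi), 1)
  expect_equal(area_to_radius(81.71), 5.10, tolerance = 1e-3)
  expect_equal(area_to_radius(0), 0)
  expect_error(area_to_radius(-1), ">= 0")

  expect_equal(ring_width(pi, 3 * pi), 1)
  expect_equal(ring_width(10, 0), 0)
  # a ring 1.82x wider than the core radius implies the area ratio
  r <- 5.1
  A_core <- pi * r^2
  A_ring <- pi * (r * 2.82)^2 - A_core
  expect_equal(A_ring / A_core, (1 + 1.82)^2 - 1, tolerance = 1e-12)
  expect_equal(A_ring / A_core, 6.9524, tolerance = 1e-4)
  expect_equal(ring_width(A_core, A_ring) / r, 1.82, tolerance = 1e-12)

  expect_equal(plaque_volume_ratio(15.21, 5.1), (15.21 / 5.1)^3)
})

test_that("concentric ROIs nest with the 1.82 ring factor", {
  roi <- build_concentric_rois(center = c(20, 20), core_radius = 5)
  expect_equal(roi$ring_outer_radius, 14.1)
  expect_equal(roi$out_outer_radius, 28.2)
  expect_equal(unname(roi$areas["Amyloid"]), pi * 25)
  # areas tile the out disk exactly
  expect_equal(sum(roi$areas), pi * roi$out_outer_radius^2)

  expect_error(build_concentric_rois(center = c(0, 0), core_radius = 5,
                                     ring_factor = 0), "ring_factor")
  expect_warning(build_concentric_rois(center = c(10, 10), core_radius = 5,
                                       field = c(20, 20)), "clipped")
})

test_that("mask-based and parametric cores give consistent ROIs", {
  ps <- 0.2
  mask <- matrix(0, 200, 200)
  rows <- matrix(seq_len(200), 200, 200)
  cols <- matrix(seq_len(200), 200, 200, byrow = TRUE)
  ctr <- 100
  mask[(rows - ctr)^2 + (cols - ctr)^2 <= (5 / ps)^2] <- 1
  roi_m <- build_concentric_rois(core_mask = mask, pixel_size = ps)
  roi_p <- build_concentric_rois(center = (c(ctr, ctr) - 1) * ps,
                                 core_radius = roi_m$core_radius)
  expect_equal(roi_m$core_radius, 5, tolerance = 0.02)
  expect_equal(roi_m$ring_outer_radius, roi_p$ring_outer_radius,
               tolerance = 1e-9)
  # region areas agree within discretization (1-px boundary band)
  expect_equal(unname(roi_m$areas["Ring"]), unname(roi_p$areas["Ring"]),
               tolerance = 0.05)
})

test_that("localization densities are unbiased for uniform points", {
  roi <- build_concentric_rois(center = c(28.2, 28.2), core_radius = 5)
  empty <- localization_density(matrix(numeric(0), ncol = 2), roi)
  expect_true(all(empty$density == 0))

  set.seed(50)
  n <- 20000
  pts <- cbind(runif(n, 0, 56.4), runif(n, 0, 56.4))
  dens <- localization_density(pts, roi)
  intensity <- n / 56.4^2
  for (i in 1:3) {
    se <- sqrt(intensity / dens$area_um2[i])
    expect_lt(abs(dens$density[i] - intensity), 3 * se)
  }
  expect_equal(penetrability_ratio(dens, "Out/Ring"), 1, tolerance = 0.05)

  core_only <- localization_density(cbind(28.2, 28.2), roi)
  expect_equal(core_only$n_locs[core_only$region != "Amyloid"], c(0L, 0L))
  expect_warning(
    expect_true(is.na(penetrability_ratio(core_only, "Out/Ring"))),
    "zero density")
})

test_that("penetrability ratio divides outer by inner density", {
  dens <- data.frame(region = c("Out", "Ring", "Amyloid"),
                     n_locs = c(20L, 10L, 5L),
                     area_um2 = c(10, 10, 10),
                     density = c(2, 1, 0.5))
  expect_equal(penetrability_ratio(dens, "Out/Ring"), 2)
  expect_equal(penetrability_ratio(dens, "Ring/Amyloid"), 2)
  eq <- dens; eq$density <- 1
  expect_equal(penetrability_ratio(eq, "Out/Ring"), 1)
})

test_that("max projection is the pixel-wise maximum", {
  a <- matrix(0, 4, 4); a[1, 1] <- 5
  b <- matrix(0, 4, 4); b[3, 2] <- 7
  stack <- simplify2array(list(a, b))
  mp <- max_projection(stack)
  expect_equal(mp[1, 1], 5); expect_equal(mp[3, 2], 7)
  expect_identical(max_projection(simplify2array(list(a, a))), a)
  expect_identical(max_projection(a), a)
})

test_that("isodata threshold is the intermeans fixed point", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  expect_equal(isodata_threshold(img), 105)
  expect_equal(isodata_threshold(img + 17), 105 + 17)
  expect_error(isodata_threshold(matrix(3, 5, 5)), "constant")

  # bimodal Gaussian mixture at 6 sigma separation: < 5% misclassification
  set.seed(51)
  v <- c(rnorm(5000, 100, 10), rnorm(5000, 160, 10))
  t <- isodata_threshold(matrix(v, 100, 100))
  mis <- (sum(v[1:5000] > t) + sum(v[5001:10000] <= t)) / 10000
  expect_lt(mis, 0.05)
})

test_that("wand selection picks the seeded 8-connected component", {
  m <- matrix(0, 10, 10)
  m[2:4, 2:4] <- 1          # blob A
  m[7:9, 7:9] <- 1          # blob B
  sel <- wand_select(m, c(3, 3))
  expect_equal(sum(sel), 9)
  expect_equal(sum(sel[7:9, 7:9]), 0)
  # diagonal touching is connected
  d <- matrix(0, 5, 5); d[2, 2] <- 1; d[3, 3] <- 1
  expect_equal(sum(wand_select(d, c(2, 2))), 2)
  expect_error(wand_select(m, c(1, 1)), "background")
})

test_that("circularity separates disks from filaments", {
  Cd <- circularity(disk_mask(50))
  expect_gt(Cd, 0.28)
  bar <- matrix(0, 210, 7); bar[6:205, 4] <- 1
  Cb <- circularity(bar)
  expect_lte(Cb, 0.14)
  expect_equal(Cb, 4 * pi * 200 / 402^2, tolerance = 0.02)
  expect_warning(single <- circularity({
    s <- matrix(0, 5, 5); s[3, 3] <- 1; s
  }), "single-pixel")
  expect_equal(single, 4 * pi / 16)
  expect_error(circularity(matrix(0, 5, 5)), "empty")
})

test_that("circularity is invariant to translation and rotation", {
  m <- generate_plaque_mask("intermediate", 128, seed = 52)
  C0 <- circularity(m)
  shifted <- matrix(0, 140, 140)
  shifted[7:134, 9:136] <- m
  expect_equal(circularity(shifted), C0, tolerance = 1e-9)
  expect_equal(circularity(t(m)[ncol(m):1, ]), C0, tolerance = 1e-9)
  # discretization error shrinks as the disk grows
  errs <- vapply(c(10, 25, 60), function(r)
    abs(circularity(disk_mask(r)) - circularity(disk_mask(120))), numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("phenotype classification uses the 0.14 / 0.28 boundaries", {
  expect_identical(classify_phenotype(0.10), "filamentous")
  expect_identical(classify_phenotype(0.20), "intermediate")
  expect_identical(classify_phenotype(0.29), "compact")
  expect_identical(classify_phenotype(0.14), "filamentous")
  expect_identical(classify_phenotype(0.28), "intermediate")
  # monotone and total on [0, inf)
  cls <- classify_phenotype(seq(0, 1.2, by = 0.01))
  lev <- c(filamentous = 1, intermediate = 2, compact = 3)
  expect_true(all(diff(lev[cls]) >= 0))
})

test_that("log-normality check passes log-normal and rejects uniform", {
  set.seed(53)
  expect_true(lognormality_check(rlnorm(10000, 3, 0.8))$pass)
  expect_false(lognormality_check(runif(10000, 1, 10))$pass)
  expect_error(lognormality_check(rlnorm(5)), "at least 8")
  expect_error(lognormality_check(c(rlnorm(10), -1)), "positive")
})
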