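# Patch morphometry, macropinosome volumetry, and target-shape metrics.

perimeter_samples <- function(P = 24.4, spacing = 0.05) {
  s <- seq(0, P, by = spacing)
  s[s < P]
}

test_that("a contiguous high arc is reported with its size and fraction", {
  s <- perimeter_samples()
  intensity <- ifelse(s >= 3 & s < 16.4, 100, 10)
  ps <- detect_patches(s, intensity, 24.4, background_mean = 10,
                       background_sd = 2)
  st <- patch_stats(ps)
  expect_equal(st$count, 1L)
  expect_equal(st$sizes, 13.4, tolerance = 0.01)
  expect_equal(st$perimeter_fraction, 13.4 / 24.4, tolerance = 0.002)
})

test_that("no samples above threshold gives an empty patch set", {
  s <- perimeter_samples()
  ps <- detect_patches(s, rep(10, length(s)), 24.4, 10, 2)
  st <- patch_stats(ps)
  expect_equal(st$count, 0L)
  expect_equal(st$perimeter_fraction, 0)
  expect_equal(st$sizes, numeric(0))
})

test_that("a patch spanning the arc-length origin is one patch, not two", {
  s <- perimeter_samples(P = 20, spacing = 0.1)
  # high arc from 17 um across the wrap to 4 um
  intensity <- ifelse(s >= 17 | s < 4, 100, 10)
  ps <- detect_patches(s, intensity, 20, 10, 2)
  st <- patch_stats(ps)
  expect_equal(st$count, 1L)
  expect_equal(st$sizes, 7, tolerance = 0.11)
  # brute-force circular run enumeration agrees on the run structure
  runs <- oracle_circular_runs(intensity > 10 + 2 * 2)
  expect_equal(length(runs), 1L)
  expect_equal(length(runs[[1]]) * 0.1, st$sizes, tolerance = 0.11)
})

test_that("gap merging and minimum-arc filtering behave as configured", {
  s <- perimeter_samples(P = 20, spacing = 0.05)
  intensity <- rep(10, length(s))
  intensity[s >= 2 & s < 5] <- 100     # patch 1
  intensity[s >= 5.3 & s < 8] <- 100   # 0.3 um gap -> merged
  intensity[s >= 12 & s < 12.5] <- 100 # 0.5 um arc -> dropped (min 1.0)
  ps <- detect_patches(s, intensity, 20, 10, 2,
                       threshold_k = 2, min_arc = 1, merge_gap = 0.5)
  st <- patch_stats(ps)
  expect_equal(st$count, 1L)
  expect_equal(st$sizes, 6, tolerance = 0.11)
})

test_that("patch stats cover the null and saturated cases", {
  st <- patch_stats(patch_set(20, matrix(c(0, 5.6), 1, 2)))
  expect_equal(st$sizes, 5.6)
  expect_equal(st$perimeter_fraction, 0.28)
  full <- patch_stats(patch_set(20, matrix(c(0, 20 - 1e-12), 1, 2)))
  expect_equal(full$perimeter_fraction, 1, tolerance = 1e-9)
})

test_that("patch detection is invariant to rotation of the arc-length origin", {
  set.seed(7)
  s <- perimeter_samples(P = 30, spacing = 0.1)
  n <- length(s)
  for (rep_i in 1:25) {
    intensity <- ifelse(runif(n) < 0.3, 100, 10)
    base <- patch_stats(detect_patches(s, intensity, 30, 10, 2))
    rot <- sample(n, 1)
    ir <- c(intensity[rot:n], intensity[seq_len(rot - 1L)])
    st <- patch_stats(detect_patches(s, ir, 30, 10, 2))
    expect_equal(st$perimeter_fraction, base$perimeter_fraction,
                 tolerance = 1e-9)
    expect_equal(st$count, base$count)
    expect_equal(sort(st$sizes), sort(base$sizes), tolerance = 1e-9)
    expect_true(st$perimeter_fraction >= 0 && st$perimeter_fraction <= 1)
  }
})

test_that("sphere volume is the exact cubic map", {
  expect_equal(sphere_volume(2), 4 * pi / 3)
  expect_equal(sphere_volume(1), pi / 6)
  v15 <- sphere_volume(1.5)
  expect_true(v15 > pi / 6 && v15 < 4 * pi / 3)
  expect_equal(sphere_volume(2 * 1.3), 8 * sphere_volume(1.3))
  expect_error(sphere_volume(-1), class = "engulfquant_param_error")
})

test_that("macropinosome stats summarize per cell and per cohort", {
  spots <- data.frame(cell_id = "c1", spot_id = 1:2, diameter_um = c(1, 2))
  st <- macropinosome_stats(spots)
  expect_equal(st$per_cell$mean_volume_um3, (pi / 6 + 4 * pi / 3) / 2,
               tolerance = 1e-9)
  expect_equal(st$per_cell$n_spots, 2L)
  # degenerate diameters at 1.24 um give ~1 um^3 mean volume
  g <- generate_spot_table(spot_table_params(n_cells = 20,
                                             diameter_log_mean = log(1.24),
                                             diameter_log_sd = 0, seed = 3))
  cg <- macropinosome_stats(g$spots, all_cells = g$cell_ids)
  expect_equal(cg$cohort$mean_volume_um3, (pi / 6) * 1.24^3,
               tolerance = 1e-9)
  expect_equal(cg$cohort$n_cells, 20L)
  # empty table
  e <- macropinosome_stats(data.frame(cell_id = character(),
                                      spot_id = integer(),
                                      diameter_um = numeric()))
  expect_equal(nrow(e$per_cell), 0L)
  # zero-spot cells are counted but excluded from the volume mean
  z <- macropinosome_stats(spots, all_cells = c("c1", "c2"))
  expect_equal(z$cohort$n_cells_no_spots, 1L)
  expect_equal(z$cohort$mean_count, 1.0)
  expect_equal(z$cohort$mean_volume_um3, st$cohort$mean_volume_um3)
})

test_that("feret diameter matches the all-pairs oracle on a rectangle", {
  mask <- matrix(0, 20, 20)
  mask[5:7, 4:13] <- 1              # 10 x 3 px rectangle
  expect_equal(feret_diameter(mask, 1), sqrt(9^2 + 2^2))
  expect_equal(feret_diameter(mask, 1), oracle_feret(mask, 1))
  # translation invariance
  mask2 <- matrix(0, 20, 20)
  mask2[11:13, 6:15] <- 1
  expect_equal(feret_diameter(mask2, 1), feret_diameter(mask, 1))
  # lattice rotation by 90 degrees
  expect_equal(feret_diameter(t(mask), 1), feret_diameter(mask, 1))
})

test_that("feret and min caliper agree with oracles on random blobs", {
  set.seed(11)
  for (i in 1:8) {
    sh <- generate_shape_image(shape_image_params(
      n_objects = 1, long_axis = runif(1, 2, 5),
      aspect_ratio = runif(1, 1, 3), pixel_size = 0.1, seed = i))
    mask <- sh$mask == 1
    expect_equal(feret_diameter(mask, 0.1), oracle_feret(mask, 0.1),
                 tolerance = 1e-12)
  }
})

test_that("feret of a rasterized circle and a rotated ellipse behave", {
  sh <- generate_shape_image(shape_image_params(n_objects = 1, long_axis = 3,
                                                aspect_ratio = 1,
                                                pixel_size = 0.1,
                                                random_orientation = FALSE,
                                                seed = 1))
  expect_lt(abs(feret_diameter(sh$mask == 1, 0.1) - 3), 0.1)
  # rotation by 37 degrees changes feret by < 2 px
  f0 <- feret_diameter(generate_shape_image(shape_image_params(
    n_objects = 1, long_axis = 4, aspect_ratio = 2, pixel_size = 0.1,
    random_orientation = FALSE, orientation = 0, seed = 1))$mask == 1, 0.1)
  f37 <- feret_diameter(generate_shape_image(shape_image_params(
    n_objects = 1, long_axis = 4, aspect_ratio = 2, pixel_size = 0.1,
    random_orientation = FALSE, orientation = 37 * pi / 180,
    seed = 1))$mask == 1, 0.1)
  expect_lt(abs(f0 - f37), 0.2)
})

test_that("shape classification separates spheres from stretched beads", {
  sh <- generate_shape_image(shape_image_params(n_objects = 10,
                                                long_axis = 3,
                                                aspect_ratio = c(1, 2.6),
                                                pixel_size = 0.1, seed = 4))
  sm <- shape_metrics(sh$mask, 0.1)
  truth <- sh$ground_truth$parameter_record$objects$true_class
  expect_identical(sm$shape_class, truth)
  # degenerate single-pixel object refuses classification
  tiny <- matrix(0, 5, 5); tiny[3, 3] <- 1
  expect_error(classify_shape(shape_object(tiny, 0.1)),
               class = "engulfquant_validation_error")
})

test_that("bead counts summarize per cell and per cohort", {
  bc <- bead_counts(list(c1 = c("spherical", "spherical", "ellipsoid")))
  expect_equal(bc$per_cell$n_spherical, 2L)
  expect_equal(bc$per_cell$n_ellipsoid, 1L)
  empty <- bead_counts(list(c1 = character(), c2 = character()))
  expect_equal(empty$mean_spherical, 0)
  expect_true(is.na(empty$uptake_ratio))
  # Monte-Carlo: Poisson(2) spheres and Poisson(1) ellipsoids per cell
  set.seed(0)
  cells <- lapply(1:50, function(i) {
    c(rep("spherical", rpois(1, 2)), rep("ellipsoid", rpois(1, 1)))
  })
  bc <- bead_counts(cells)
  sem_s <- sd(bc$per_cell$n_spherical) / sqrt(50)
  sem_e <- sd(bc$per_cell$n_ellipsoid) / sqrt(50)
  expect_lt(abs(bc$mean_spherical - 2), 3 * sem_s)
  expect_lt(abs(bc$mean_ellipsoid - 1), 3 * sem_e)
})
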