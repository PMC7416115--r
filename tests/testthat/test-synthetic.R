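# Generators: determinism, degenerate cases, and agreement between the
# rendered artifacts and their ground-truth records.

test_that("every generator is bit-identical under a fixed seed", {
  a <- generate_cup_image(cup_image_params(noise_sd = 30, seed = 11))
  b <- generate_cup_image(cup_image_params(noise_sd = 30, seed = 11))
  expect_identical(a$image, b$image)
  expect_identical(a$contour, b$contour)
  expect_identical(a$ground_truth, b$ground_truth)

  pa <- generate_profile_pair(profile_pair_params(noise_sd = 20, seed = 4))
  pb <- generate_profile_pair(profile_pair_params(noise_sd = 20, seed = 4))
  expect_identical(pa$profile_A$intensities, pb$profile_A$intensities)

  ta <- generate_tracks(track_params(n_tracks = 4, seed = 9))
  tb <- generate_tracks(track_params(n_tracks = 4, seed = 9))
  expect_identical(ta$tracks$tracks[[3]]$positions,
                   tb$tracks$tracks[[3]]$positions)

  sa <- generate_spot_table(spot_table_params(seed = 2))
  sb <- generate_spot_table(spot_table_params(seed = 2))
  expect_identical(sa$spots, sb$spots)

  ma <- generate_shape_image(shape_image_params(n_objects = 6, seed = 5))
  mb <- generate_shape_image(shape_image_params(n_objects = 6, seed = 5))
  expect_identical(ma$mask, mb$mask)

  ka <- generate_kinetics(kinetics_params(noise_sd = 1, seed = 3))
  kb <- generate_kinetics(kinetics_params(noise_sd = 1, seed = 3))
  expect_identical(ka$series$gdp_percent, kb$series$gdp_percent)
})

test_that("uniform cup (E_tip = E_base = 1) renders a flat membrane", {
  g <- generate_cup_image(cup_image_params(tip_enrichment = 1,
                                           base_enrichment = 1,
                                           noise_sd = 0, seed = 1))
  ls <- extract_linescan(g$image, g$contour, pixel_size = 0.1)
  # all membrane samples equal the reference intensity (rasterization tol)
  expect_lt(diff(range(ls$intensities)) / mean(ls$intensities), 0.02)
  ep <- fold_enrichment(ls)
  expect_true(all(abs(ep$fold - 1) < 0.02))
})

test_that("cup generator validates parameters and geometry", {
  expect_error(cup_image_params(membrane_intensity = 50,
                                background_level = 100),
               class = "engulfquant_param_error")
  expect_error(cup_image_params(cup_arc_fraction = 0.6),
               class = "engulfquant_param_error")
  expect_error(
    generate_cup_image(cup_image_params(cell_radius = 6,
                                        image_shape = c(40, 40))),
    class = "engulfquant_geometry_error")
})

test_that("profile pair with zero offset gives identical normalized channels", {
  pp <- generate_profile_pair(profile_pair_params(channel_offset = 0,
                                                  plateau_A = 500,
                                                  plateau_B = 900,
                                                  background_A = 50,
                                                  background_B = 90,
                                                  noise_sd = 0))
  a <- (pp$profile_A$intensities - 50) / 450
  b <- (pp$profile_B$intensities - 90) / 810
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("hard-edged profile pair is an exact step at the edge position", {
  pp <- generate_profile_pair(profile_pair_params(edge_softness = 0,
                                                  edge_position = 5,
                                                  noise_sd = 0))
  x <- pp$profile_A$positions
  i <- pp$profile_A$intensities
  expect_true(all(i[x < 5] == 500))
  expect_true(all(i[x >= 5] == 50))
})

test_that("offset outside the profile raises a geometry error", {
  expect_error(profile_pair_params(edge_position = 5, channel_offset = 4,
                                   profile_length = 8),
               class = "engulfquant_geometry_error")
})

test_that("spot table degenerate and empty cases behave", {
  g <- generate_spot_table(spot_table_params(n_cells = 5,
                                             spots_per_cell_mean = 4,
                                             diameter_log_mean = log(2),
                                             diameter_log_sd = 0, seed = 1))
  expect_true(all(abs(g$spots$diameter_um - 2) < 1e-12))
  expect_equal(g$ground_truth$parameter_record$true_mean_volume_um3,
               4 * pi / 3, tolerance = 1e-12)
  empty <- generate_spot_table(spot_table_params(n_cells = 0))
  expect_equal(nrow(empty$spots), 0L)
})

test_that("conserved-volume prolate stretched from a 3 um sphere has the analytic long axis", {
  # solve a * b^2 = r^3 with a/b = 2.6: long axis = d * 2.6^(2/3)
  long_axis <- 3 * 2.6^(2 / 3)
  sh <- generate_shape_image(shape_image_params(n_objects = 5,
                                                long_axis = long_axis,
                                                aspect_ratio = 2.6,
                                                pixel_size = 0.1, seed = 8))
  sm <- shape_metrics(sh$mask, 0.1)
  expect_true(all(abs(sm$feret_um - long_axis) <= 0.2))
})

test_that("shape packing failure raises a packing error", {
  expect_error(
    generate_shape_image(shape_image_params(n_objects = 50, long_axis = 3,
                                            pixel_size = 0.1,
                                            image_size_um = 8, seed = 1)),
    class = "engulfquant_geometry_error")
})

test_that("fully biased noiseless tracks run straight up the gradient", {
  g <- generate_tracks(track_params(n_tracks = 3, n_steps = 20,
                                    mean_speed = 5, dt = 0.5, speed_sd = 0,
                                    directional_bias = 1, seed = 2))
  for (tr in g$tracks$tracks) {
    expect_equal(track_speed(tr), 5.0, tolerance = 1e-12)
    expect_equal(chemotactic_index(tr), 1.0, tolerance = 1e-12)
  }
})

test_that("unbiased track cohort has near-zero mean chemotactic index", {
  # Monte-Carlo check: 1000 unbiased correlated walks, seed 0
  g <- generate_tracks(track_params(n_tracks = 1000, n_steps = 30,
                                    directional_bias = 0, seed = 0))
  cs <- cohort_summary(g$tracks)
  ci <- cs$cohort$ci
  expect_lt(abs(ci$mean), 3 * ci$sem + 0.01)
})

test_that("kinetics series is exactly linear below saturation", {
  g <- generate_kinetics(kinetics_params(n_points = 6, dt = 1,
                                         initial_rate = 7,
                                         saturation_level = 100,
                                         noise_sd = 0))
  expect_equal(diff(g$series$gdp_percent), rep(7, 5), tolerance = 1e-12)
  expect_error(kinetics_params(n_points = 3),
               class = "engulfquant_param_error")
  # minimum length series is accepted by the rate fitter
  g4 <- generate_kinetics(kinetics_params(n_points = 4, initial_rate = 3,
                                          saturation_level = 100))
  expect_equal(linear_rate(g4$series)$rate, 3, tolerance = 1e-12)
})
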