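# Fold-enrichment profile quantification: normalization formula,
# resampling, averaging, tip statistic, and image extraction.

make_profile <- function(intens, background = 10, reference = 110,
                         spacing = 0.1) {
  linescan_profile(positions = seq(0, by = spacing,
                                   length.out = length(intens)),
                   intensities = intens, background = background,
                   reference_intensity = reference)
}

test_that("fold enrichment implements (I - B) / (I_np - B)", {
  p <- make_profile(rep(110, 20))          # I = I_np everywhere
  expect_equal(fold_enrichment(p)$fold, rep(1, 20))
  p <- make_profile(rep(10, 20))           # I = B everywhere
  expect_equal(fold_enrichment(p)$fold, rep(0, 20))
  p <- make_profile(c(rep(110, 10), 2 * 110 - 10, rep(110, 9)))
  expect_equal(fold_enrichment(p)$fold[11], 2.0)
  # grid endpoints are 0 and 1
  g <- fold_enrichment(p)$grid
  expect_identical(c(g[1], g[length(g)]), c(0, 1))
})

test_that("normalization is undefined when reference does not exceed background", {
  expect_error(make_profile(rep(50, 20), background = 10, reference = 5),
               class = "engulfquant_param_error")
})

test_that("resampling matches a brute-force piecewise-linear oracle", {
  set.seed(42)
  p <- make_profile(runif(17, 50, 300))
  ep <- fold_enrichment(p)
  rs <- resample_profile(ep, 1000)
  expect_equal(rs$fold, oracle_interp(ep$grid, ep$fold, rs$grid),
               tolerance = 1e-12)
  # endpoints preserved exactly
  expect_identical(rs$fold[1], ep$fold[1])
  expect_identical(rs$fold[1000], ep$fold[17])
})

test_that("resampling is exact on constants and ramps, and idempotent", {
  const <- resample_profile(fold_enrichment(make_profile(rep(120, 9))), 100)
  expect_equal(const$fold, rep(1.1, 100))
  ramp <- fold_enrichment(make_profile(seq(10, 110, length.out = 11)))
  rs <- resample_profile(ramp, 501)
  expect_equal(rs$fold, rs$grid, tolerance = 1e-12)
  once <- resample_profile(ramp, 250)
  twice <- resample_profile(once, 250)
  expect_equal(twice$fold, once$fold, tolerance = 1e-12)
  expect_error(resample_profile(ramp, 1), class = "engulfquant_param_error")
})

test_that("profile averaging gives pointwise mean and sample sd", {
  p1 <- resample_profile(fold_enrichment(make_profile(rep(10, 5))), 100)
  p2 <- resample_profile(fold_enrichment(make_profile(rep(210, 5))), 100)
  m <- average_profiles(list(p1, p2))
  expect_equal(m$mean, rep(1, 100))          # folds 0 and 2 -> mean 1
  expect_equal(m$sd, rep(sqrt(2), 100))      # sample sd, n - 1
  expect_equal(m$n_cups, 2L)
  # k identical profiles
  m3 <- average_profiles(list(p1, p1, p1))
  expect_equal(m3$mean, p1$fold)
  expect_equal(m3$sd, rep(0, 100))
  # single profile: sd 0 by convention, flagged
  m1 <- average_profiles(list(p2))
  expect_equal(m1$sd, rep(0, 100))
  expect_true(isTRUE(attr(m1, "single_profile")))
  # order invariance
  mperm <- average_profiles(list(p2, p1))
  expect_equal(mperm$mean, m$mean)
  expect_equal(mperm$sd, m$sd)
  # errors
  expect_error(average_profiles(list()), class = "engulfquant_param_error")
  pg <- resample_profile(fold_enrichment(make_profile(rep(10, 5))), 99)
  expect_error(average_profiles(list(p1, pg)),
               class = "engulfquant_validation_error")
})

test_that("tip enrichment averages the leading profile fraction", {
  fold <- c(rep(3, 100), rep(1, 900))
  ep <- structure(list(grid = seq(0, 1, length.out = 1000), fold = fold,
                       source_id = "x", native = FALSE),
                  class = "enrichment_profile")
  expect_equal(tip_enrichment(ep, symmetrize = FALSE), 3.0)
  expect_equal(tip_enrichment(ep, symmetrize = TRUE), 2.0) # far tip is 1
  uni <- structure(list(grid = seq(0, 1, length.out = 1000),
                        fold = rep(1, 1000), source_id = "x",
                        native = FALSE), class = "enrichment_profile")
  expect_equal(tip_enrichment(uni), 1.0)
  expect_error(tip_enrichment(ep, tip_fraction = 0.7),
               class = "engulfquant_param_error")
})

test_that("extraction width has little effect on noise-free fold profiles", {
  g <- generate_cup_image(cup_image_params(tip_enrichment = 2,
                                           base_enrichment = 1.5,
                                           noise_sd = 0, seed = 3))
  f1 <- fold_enrichment(extract_linescan(g$image, g$contour, 0.1, width = 1))
  f3 <- fold_enrichment(extract_linescan(g$image, g$contour, 0.1, width = 3))
  expect_equal(length(f1$fold), length(f3$fold))
  expect_lt(max(abs(f1$fold - f3$fold)), 0.25)   # rasterization tolerance
  expect_lt(abs(mean(f1$fold) - mean(f3$fold)), 0.03)
})

test_that("swapping the anchors reverses the extracted profile", {
  g <- generate_cup_image(cup_image_params(noise_sd = 0, seed = 6))
  fwd <- extract_linescan(g$image, g$contour, 0.1,
                          anchors = g$contour$tip_indices)
  rev_ <- extract_linescan(g$image, g$contour, 0.1,
                           anchors = rev(g$contour$tip_indices))
  expect_equal(rev_$intensities, rev(fwd$intensities), tolerance = 1e-12)
  expect_equal(rev_$background, fwd$background)
})

test_that("anchor and degeneracy errors are raised", {
  g <- generate_cup_image(cup_image_params(noise_sd = 0, seed = 6))
  expect_error(extract_linescan(g$image, g$contour, 0.1,
                                anchors = c(1, 10 * nrow(g$contour$points))),
               class = "engulfquant_geometry_error")
  expect_error(extract_linescan(g$image, g$contour, 0.1,
                                anchors = c(1, 4)),
               class = "engulfquant_param_error")  # < 10 samples
  expect_error(extract_linescan(g$image, g$contour, 0.1, width = 2),
               class = "engulfquant_param_error")
})

test_that("fold enrichment is invariant under affine intensity gain a*I + b", {
  g <- generate_cup_image(cup_image_params(tip_enrichment = 2.5,
                                           base_enrichment = 1.5,
                                           noise_sd = 0, seed = 12))
  f0 <- fold_enrichment(extract_linescan(g$image, g$contour, 0.1))
  img2 <- 3.7 * g$image + 55        # background and reference re-measured
  f1 <- fold_enrichment(extract_linescan(img2, g$contour, 0.1))
  expect_equal(f1$fold, f0$fold, tolerance = 1e-9)
})
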