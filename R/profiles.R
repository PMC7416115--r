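#' Membrane linescan profile
#'
#' A fluorescence intensity profile sampled along the cell membrane,
#' together with the two normalization constants the fold-enrichment
#' calculation needs: the local extracellular background `B` and the
#' reference intensity `I_np` of a non-protrusive stretch of membrane.
#'
#' @param positions micrometres from the profile start, strictly increasing.
#' @param intensities raw intensities, a.u., same length as `positions`.
#' @param channel channel label.
#' @param background local background intensity `B`, a.u.
#' @param reference_intensity non-protrusive membrane intensity `I_np`,
#'   a.u.; must exceed `background`.
#' @param sample_spacing nominal sample spacing, micrometres.
#' @return An object of class `"linescan_profile"`.
#' @export
linescan_profile <- function(positions, intensities, channel = "ch1",
                             background, reference_intensity,
                             sample_spacing = NULL) {
  check_that(length(positions) == length(intensities) &&
               length(positions) >= 2,
             "positions and intensities must have equal length >= 2")
  check_that(all(is.finite(positions)) && all(diff(positions) > 0),
             "positions must be finite and strictly increasing")
  check_that(all(is.finite(intensities)) && all(intensities >= 0),
             "intensities must be finite and >= 0")
  check_that(is.numeric(background) && background >= 0,
             "background must be >= 0")
  check_that(reference_intensity > background,
             "reference_intensity must exceed background")
  if (is.null(sample_spacing)) sample_spacing <- stats::median(diff(positions))
  structure(list(positions = positions, intensities = intensities,
                 channel = channel, background = background,
                 reference_intensity = reference_intensity,
                 sample_spacing = sample_spacing),
            class = "linescan_profile")
}

#' @export
print.linescan_profile <- function(x, ...) {
  cat(sprintf(
    "<linescan_profile> channel %s, %d samples over %.2f um (B = %.1f, I_np = %.1f)\n",
    x$channel, length(x$positions), diff(range(x$positions)),
    x$background, x$reference_intensity))
  invisible(x)
}

#' Extract a membrane linescan from a two-channel image
#'
#' Samples the image along the contour between two anchor points (by
#' default the two cup tips, i.e. the tip-to-tip path through the cup
#' interior), averaging over `width` pixels normal to the membrane at
#' each sample. The local background is measured in a band
#' `background_band[1]`-`background_band[2]` pixels outside the cell
#' adjacent to the cup, and the reference intensity over the contour's
#' non-protrusive reference arc using the same width-averaged sampling.
#'
#' @param image numeric array (rows x cols x channels) or matrix.
#' @param contour a [cup_contour()] in micrometres.
#' @param pixel_size micrometres per pixel.
#' @param channel channel index to sample.
#' @param anchors two contour point indices bounding the path; default
#'   the contour's tip indices. Swapping the anchors reverses the profile.
#' @param width averaging width normal to the membrane, pixels (odd >= 1);
#'   the band is sampled at half-pixel steps with bilinear interpolation.
#' @param background_band inner/outer radius of the extracellular
#'   background band, pixels. The default starts 4 px out so the
#'   membrane's Gaussian cross-section (1 px sigma) contributes
#'   negligibly.
#' @param trim_px length trimmed from each end of the path, pixels.
#'   At a cup tip the membrane folds back on itself, so samples within
#'   the blur length of the corner mix both membrane branches; they are
#'   excluded rather than reported. Set to 0 to keep the full path.
#' @return A [linescan_profile()] sampled at native pixel spacing.
#' @export
extract_linescan <- function(image, contour, pixel_size, channel = 1L,
                             anchors = NULL, width = 5L,
                             background_band = c(4, 7), trim_px = 3) {
  check_that(pixel_size > 0, "pixel_size must be positive")
  check_that(width >= 1 && width %% 2 == 1, "width must be odd and >= 1")
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  check_that(channel >= 1 && channel <= dim(image)[3],
             "channel index out of range")
  img <- image[, , channel]
  n_pts <- nrow(contour$points)
  if (is.null(anchors)) anchors <- contour$tip_indices
  anchors <- as.integer(anchors)
  check_that(length(anchors) == 2 && !anyNA(anchors) &&
               all(anchors >= 1 & anchors <= n_pts) &&
               anchors[1] != anchors[2],
             "anchors must be two distinct contour point indices",
             abort = abort_geometry)
  reversed <- anchors[1] > anchors[2]
  a <- sort(anchors)
  path <- resample_contour_path(contour, a[1], a[2], spacing = pixel_size)
  if (trim_px > 0) {
    keep <- path$pos >= trim_px * pixel_size &
      path$pos <= path$pos[length(path$pos)] - trim_px * pixel_size
    path$pos <- path$pos[keep] - path$pos[keep][1]
    path$xy <- path$xy[keep, , drop = FALSE]
  }
  if (length(path$pos) < 10) {
    abort_param("profile has fewer than 10 samples; degenerate path")
  }
  centroid <- colMeans(contour$points)
  normals <- path_normals(path$xy, centroid)
  half <- (width - 1) / 2
  offsets <- seq(-half, half, by = 0.5) * pixel_size
  sample_mean <- function(xy, nrm) {
    acc <- 0
    for (o in offsets) {
      px <- (xy[, 1] + o * nrm[, 1]) / pixel_size
      py <- (xy[, 2] + o * nrm[, 2]) / pixel_size
      acc <- acc + bilinear_sample(img, px, py)
    }
    acc / length(offsets)
  }
  intens <- sample_mean(path$xy, normals)

  # Background: band outside the cell adjacent to the cup, sampled from
  # the central 60% of the path (avoids the tip corners).
  n <- nrow(path$xy)
  core <- seq(max(1L, ceiling(0.2 * n)), floor(0.8 * n))
  bg_off <- seq(background_band[1], background_band[2], by = 1) * pixel_size
  bg_vals <- unlist(lapply(bg_off, function(o) {
    px <- (path$xy[core, 1] + o * normals[core, 1]) / pixel_size
    py <- (path$xy[core, 2] + o * normals[core, 2]) / pixel_size
    bilinear_sample(img, px, py)
  }))
  background <- mean(bg_vals)

  # Reference intensity: width-averaged membrane signal over the
  # non-protrusive reference arc.
  ref <- resample_contour_path(contour, contour$reference_arc[1],
                               contour$reference_arc[2], spacing = pixel_size)
  ref_norm <- path_normals(ref$xy, centroid)
  reference_intensity <- mean(sample_mean(ref$xy, ref_norm))

  if (reversed) intens <- rev(intens)
  linescan_profile(positions = path$pos, intensities = intens,
                   channel = as.character(channel), background = background,
                   reference_intensity = reference_intensity,
                   sample_spacing = pixel_size)
}

#' Fold-enrichment profile from a raw linescan
#'
#' Converts raw intensities to fold-enrichment,
#' `E = (I - B) / (I_np - B)`, and rescales positions to the normalized
#' arc coordinate `[0, 1]` by the total path length. The result stays on
#' the native sampling grid; use [resample_profile()] to move it to the
#' fixed comparison grid.
#'
#' @param profile a [linescan_profile()].
#' @param source_id identifier carried through to downstream tables.
#' @return An object of class `"enrichment_profile"` with fields `grid`,
#'   `fold`, `source_id`, `native`.
#' @export
fold_enrichment <- function(profile, source_id = "cup") {
  stopifnot(inherits(profile, "linescan_profile"))
  denom <- profile$reference_intensity - profile$background
  check_that(denom > 0, "reference intensity must exceed background ",
             "(normalization would be undefined)")
  pos <- profile$positions
  grid <- (pos - pos[1]) / (pos[length(pos)] - pos[1])
  structure(list(grid = grid,
                 fold = (profile$intensities - profile$background) / denom,
                 source_id = source_id, native = TRUE),
            class = "enrichment_profile")
}

#' Resample an enrichment profile onto the fixed comparison grid
#'
#' Linear interpolation onto `n_grid` equally spaced points on `[0, 1]`
#' (endpoints included; first and last values are preserved exactly). No
#' extrapolation beyond the endpoints is performed. Resampling is
#' idempotent on the fixed grid.
#'
#' @param profile an [fold_enrichment()] result.
#' @param n_grid number of grid points (default 1000).
#' @return An `"enrichment_profile"` on the fixed grid (`native = FALSE`).
#' @export
resample_profile <- function(profile, n_grid = 1000L) {
  stopifnot(inherits(profile, "enrichment_profile"))
  check_that(n_grid >= 2, "n_grid must be >= 2")
  check_that(length(profile$grid) >= 2, "profile needs >= 2 points")
  out <- seq(0, 1, length.out = n_grid)
  fold <- stats::approx(profile$grid, profile$fold, xout = out,
                        rule = 2)$y
  fold[1] <- profile$fold[1]
  fold[n_grid] <- profile$fold[length(profile$fold)]
  structure(list(grid = out, fold = fold, source_id = profile$source_id,
                 native = FALSE),
            class = "enrichment_profile")
}

#' Average enrichment profiles across cups
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator) of
#' profiles sharing an identical grid.
#'
#' @param profiles list of `"enrichment_profile"` objects on the same grid.
#' @return An object of class `"mean_profile"` with `grid`, `mean`, `sd`,
#'   `n_cups`. With a single profile the sd is 0 by convention and the
#'   result carries attribute `single_profile = TRUE`.
#' @export
average_profiles <- function(profiles) {
  check_that(is.list(profiles) && length(profiles) >= 1,
             "need a non-empty list of profiles")
  stopifnot(all(vapply(profiles, inherits, TRUE, "enrichment_profile")))
  g <- profiles[[1]]$grid
  for (p in profiles) {
    if (length(p$grid) != length(g) || max(abs(p$grid - g)) > 1e-10) {
      abort_validation("profiles are not on an identical grid; ",
                       "resample them first")
    }
  }
  mat <- vapply(profiles, function(p) p$fold, numeric(length(g)))
  mat <- matrix(mat, nrow = length(g))
  n <- length(profiles)
  m <- rowMeans(mat)
  s <- if (n == 1) rep(0, length(g)) else apply(mat, 1, stats::sd)
  out <- structure(list(grid = g, mean = m, sd = s, n_cups = n),
                   class = "mean_profile")
  if (n == 1) attr(out, "single_profile") <- TRUE
  out
}

#' Tip enrichment of a cup profile
#'
#' Mean fold-enrichment over the leading `tip_fraction` of the profile
#' (the first 100 of 1000 grid points at defaults). Because the
#' orientation of a tip-to-tip linescan is arbitrary, the default
#' `symmetrize = TRUE` averages the leading and trailing segments so both
#' tips contribute; set `symmetrize = FALSE` to use only the designated
#' first tip.
#'
#' @param profile an `"enrichment_profile"` (normally on the fixed grid).
#' @param tip_fraction fraction of the profile counted as tip, in (0, 0.5].
#' @param symmetrize average over both ends of the profile?
#' @return Scalar fold-enrichment.
#' @export
tip_enrichment <- function(profile, tip_fraction = 0.10, symmetrize = TRUE) {
  stopifnot(inherits(profile, "enrichment_profile"))
  check_that(tip_fraction > 0 && tip_fraction <= 0.5,
             "tip_fraction must lie in (0, 0.5]")
  f <- profile$fold
  m <- ceiling(tip_fraction * length(f))
  vals <- if (symmetrize) c(f[seq_len(m)], f[seq(length(f) - m + 1, length(f))])
          else f[seq_len(m)]
  mean(vals)
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat(sprintf("<enrichment_profile> '%s', %d points (%s grid), fold %.2f-%.2f\n",
              x$source_id, length(x$grid),
              if (isTRUE(x$native)) "native" else "fixed",
              min(x$fold), max(x$fold)))
  invisible(x)
}

#' @export
print.mean_profile <- function(x, ...) {
  cat(sprintf("<mean_profile> %d cups, %d grid points, mean fold %.2f-%.2f\n",
              x$n_cups, length(x$grid), min(x$mean), max(x$mean)))
  invisible(x)
}

#' @export
plot.mean_profile <- function(x, add_sd = TRUE,
                              xlab = "normalized cup position",
                              ylab = "fold enrichment", ...) {
  graphics::plot(x$grid, x$mean, type = "l", xlab = xlab, ylab = ylab, ...)
  if (add_sd && x$n_cups > 1) {
    graphics::polygon(c(x$grid, rev(x$grid)),
                      c(x$mean + x$sd, rev(x$mean - x$sd)),
                      border = NA, col = grDevices::adjustcolor("grey", 0.5))
    graphics::lines(x$grid, x$mean)
  }
  invisible(x)
}
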