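#' Parameters for the synthetic cup-image generator
#'
#' Describes a circular cell carrying a single macropinocytic/phagocytic
#' cup, rendered as a two-channel fluorescence image. Channel 1 is the
#' probe of interest, whose membrane signal is enriched at the cup; the
#' enrichment profile runs at `tip_enrichment` over a plateau at each
#' protrusive tip, ramps linearly down to `base_enrichment` over the cup
#' base, and is 1 (no enrichment) on the non-cup membrane. Channel 2 is a
#' uniform membrane marker. The membrane is rendered with a 1-pixel-sigma
#' Gaussian cross-section so linescan extraction at width > 1 is
#' meaningful.
#'
#' @param cell_radius cell radius, micrometres.
#' @param cup_arc_fraction fraction of the cell perimeter spanned by the
#'   cup, in (0, 0.45); the cup is a circular-arc indentation whose
#'   endpoints are the protrusive tips.
#' @param tip_enrichment fold-enrichment at the protrusive tips (>= 0).
#' @param base_enrichment fold-enrichment at the cup base (>= 0).
#' @param membrane_intensity reference (non-protrusive) membrane peak
#'   intensity, arbitrary units; must exceed `background_level`.
#' @param background_level extracellular background intensity, a.u.
#' @param noise_sd standard deviation of additive Gaussian intensity
#'   noise, a.u. (applied per pixel, clipped at 0).
#' @param pixel_size micrometres per pixel.
#' @param image_shape integer (rows, cols) in pixels, or `NULL` to size
#'   the image automatically around the cell.
#' @param tip_plateau_fraction fraction of the cup arc (from each tip)
#'   held at `tip_enrichment` before the ramp begins.
#' @param base_plateau_fraction central fraction of the cup arc held at
#'   `base_enrichment`.
#' @param noise_model `"gaussian"` (additive, default) or `"poisson"`
#'   (shot noise with the noise-free image as the rate).
#' @param seed integer RNG seed; identical parameters and seed give a
#'   bit-identical image.
#'
#' @return A list of class `"cup_image_params"`.
#' @export
cup_image_params <- function(cell_radius = 6, cup_arc_fraction = 0.3,
                             tip_enrichment = 3, base_enrichment = 2,
                             membrane_intensity = 800, background_level = 100,
                             noise_sd = 0, pixel_size = 0.1,
                             image_shape = NULL,
                             tip_plateau_fraction = 0.10,
                             base_plateau_fraction = 0.30,
                             noise_model = c("gaussian", "poisson"),
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  p <- list(cell_radius = cell_radius, cup_arc_fraction = cup_arc_fraction,
            tip_enrichment = tip_enrichment, base_enrichment = base_enrichment,
            membrane_intensity = membrane_intensity,
            background_level = background_level, noise_sd = noise_sd,
            pixel_size = pixel_size, image_shape = image_shape,
            tip_plateau_fraction = tip_plateau_fraction,
            base_plateau_fraction = base_plateau_fraction,
            noise_model = noise_model, seed = as.integer(seed))
  check_that(cell_radius > 0, "cell_radius must be positive")
  check_that(cup_arc_fraction > 0 && cup_arc_fraction < 0.45,
             "cup_arc_fraction must lie in (0, 0.45)")
  check_that(tip_enrichment >= 0 && base_enrichment >= 0,
             "enrichment values must be >= 0")
  check_that(membrane_intensity > background_level && background_level >= 0,
             "need membrane_intensity > background_level >= 0")
  check_that(pixel_size > 0, "pixel_size must be positive")
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  check_that(tip_plateau_fraction > 0 && base_plateau_fraction >= 0 &&
               2 * tip_plateau_fraction + base_plateau_fraction < 1,
             "tip/base plateau fractions must leave room for the ramps")
  structure(p, class = "cup_image_params")
}

# Cup enrichment profile E(u) on the normalized cup coordinate u in [0,1]:
# tip plateaus at both ends, base plateau in the middle, linear ramps
# between. Vectorized over u.
cup_enrichment_fun <- function(u, e_tip, e_base, tip_frac, base_frac) {
  u <- pmin(u, 1 - u) * 2                      # fold: 0 at a tip, 1 at base
  lo <- 2 * tip_frac                           # plateau end on folded scale
  hi <- 1 - base_frac                          # ramp end on folded scale
  e <- numeric(length(u))
  e[u <= lo] <- e_tip
  e[u >= hi] <- e_base
  mid <- u > lo & u < hi
  e[mid] <- e_tip + (e_base - e_tip) * (u[mid] - lo) / (hi - lo)
  e
}

# Distance-to-polyline rasterizer: for every pixel within `win` pixels of
# the polyline, records the squared distance to the nearest segment and
# the signal value linearly interpolated at the projection point.
rasterize_polyline <- function(xy_px, evals, nr, nc, win = 5L) {
  best_d2 <- matrix(Inf, nr, nc)
  best_e <- matrix(0, nr, nc)
  n <- nrow(xy_px)
  for (i in seq_len(n - 1L)) {
    p1x <- xy_px[i, 1]; p1y <- xy_px[i, 2]
    p2x <- xy_px[i + 1L, 1]; p2y <- xy_px[i + 1L, 2]
    c0 <- max(1L, floor(min(p1x, p2x) - win) + 1L)
    c1 <- min(nc, ceiling(max(p1x, p2x) + win))
    r0 <- max(1L, floor(min(p1y, p2y) - win) + 1L)
    r1 <- min(nr, ceiling(max(p1y, p2y) + win))
    if (c0 > c1 || r0 > r1) next
    xc <- (c0:c1) - 0.5
    yc <- (r0:r1) - 0.5
    X <- matrix(xc, length(yc), length(xc), byrow = TRUE)
    Y <- matrix(yc, length(yc), length(xc))
    dx <- p2x - p1x; dy <- p2y - p1y
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) 0 else pmin(pmax(((X - p1x) * dx + (Y - p1y) * dy) / L2, 0), 1)
    d2 <- (X - (p1x + t * dx))^2 + (Y - (p1y + t * dy))^2
    sub_d2 <- best_d2[r0:r1, c0:c1, drop = FALSE]
    upd <- d2 < sub_d2
    if (any(upd)) {
      e <- evals[i] + t * (evals[i + 1L] - evals[i])
      sub_e <- best_e[r0:r1, c0:c1, drop = FALSE]
      sub_d2[upd] <- d2[upd]
      sub_e[upd] <- e[upd]
      best_d2[r0:r1, c0:c1] <- sub_d2
      best_e[r0:r1, c0:c1] <- sub_e
    }
  }
  list(d2 = best_d2, e = best_e)
}

#' Generate a synthetic two-channel cup image with ground truth
#'
#' Renders a circular cell with a circular-arc cup indentation. The
#' membrane intensity along the contour equals
#' `B + (I_ref - B) * E(s)`, where `E(s)` is the cup enrichment profile
#' of [cup_image_params()] (1 on the non-cup membrane), with a Gaussian
#' cross-section of 1 pixel sigma normal to the membrane. Channel 2 is a
#' uniform membrane marker (`E = 1` everywhere). The returned contour
#' carries tip anchors at both cup tips and a 3 micrometre reference arc
#' diametrically opposite the cup.
#'
#' @param params a [cup_image_params()] object.
#' @return A list with elements `image` (rows x cols x 2 array, a.u.),
#'   `contour` (a [cup_contour()]), and `ground_truth` (generator name,
#'   true parameter record and seed).
#' @export
generate_cup_image <- function(params) {
  if (!inherits(params, "cup_image_params")) {
    params <- do.call(cup_image_params, as.list(params))
  }
  p <- params
  margin_um <- 8 * p$pixel_size + 1     # membrane blur + background annulus
  extent <- 2 * (p$cell_radius + margin_um)
  if (is.null(p$image_shape)) {
    side <- ceiling(extent / p$pixel_size)
    p$image_shape <- c(side, side)
  }
  nr <- p$image_shape[1]; nc <- p$image_shape[2]
  check_that(nr * p$pixel_size >= extent && nc * p$pixel_size >= extent,
             "image too small to contain the cell plus margin",
             abort = abort_geometry)
  alpha <- pi * p$cup_arc_fraction      # half-angle subtended by the cup
  check_that(2 * cos(alpha) - 1 > 0.05,
             "cup indentation too deep for this geometry",
             abort = abort_geometry)
  cx <- nc * p$pixel_size / 2
  cy <- nr * p$pixel_size / 2
  R <- p$cell_radius

  spacing_px <- 0.5
  dtheta <- spacing_px * p$pixel_size / R
  # Cup arc: cell arc theta in [-alpha, alpha] reflected across the
  # tip-to-tip chord (x = cx + R cos(alpha)), bowing inward.
  th_cup <- seq(-alpha, alpha, by = dtheta)
  if (th_cup[length(th_cup)] < alpha) th_cup <- c(th_cup, alpha)
  chord_x <- cx + R * cos(alpha)
  cup_xy <- cbind(2 * chord_x - (cx + R * cos(th_cup)), cy + R * sin(th_cup))
  u_cup <- (th_cup + alpha) / (2 * alpha)
  e_cup <- cup_enrichment_fun(u_cup, p$tip_enrichment, p$base_enrichment,
                              p$tip_plateau_fraction, p$base_plateau_fraction)
  # Non-cup membrane: theta from alpha around to 2*pi - alpha.
  th_out <- seq(alpha, 2 * pi - alpha, by = dtheta)
  if (th_out[length(th_out)] < 2 * pi - alpha) th_out <- c(th_out, 2 * pi - alpha)
  th_out <- th_out[-1]                   # tip2 already present
  out_xy <- cbind(cx + R * cos(th_out), cy + R * sin(th_out))
  pts <- rbind(cup_xy, out_xy)
  evals <- c(e_cup, rep(1, nrow(out_xy)))

  tip_idx <- c(1L, nrow(cup_xy))
  # 3 um reference arc centered opposite the cup (theta = pi).
  ref_half <- 1.5 / R
  ref_idx <- nrow(cup_xy) + range(which(th_out >= pi - ref_half &
                                          th_out <= pi + ref_half))
  contour <- cup_contour(pts, tip_indices = tip_idx, reference_arc = ref_idx)

  xy_px <- pts / p$pixel_size
  ras <- rasterize_polyline(rbind(xy_px, xy_px[1, , drop = FALSE]),
                            c(evals, evals[1]), nr, nc)
  g <- exp(-ras$d2 / 2)                  # sigma = 1 px cross-section
  B <- p$background_level
  amp <- p$membrane_intensity - B
  ch1 <- B + amp * ras$e * g
  ch2 <- B + amp * g
  img <- with_seed(p$seed, {
    if (p$noise_model == "poisson") {
      array(c(stats::rpois(nr * nc, ch1), stats::rpois(nr * nc, ch2)),
            dim = c(nr, nc, 2))
    } else if (p$noise_sd > 0) {
      array(pmax(c(ch1 + stats::rnorm(nr * nc, 0, p$noise_sd),
                   ch2 + stats::rnorm(nr * nc, 0, p$noise_sd)), 0),
            dim = c(nr, nc, 2))
    } else {
      array(c(ch1, ch2), dim = c(nr, nc, 2))
    }
  })
  gt <- ground_truth("cup_image",
                     list(cell_radius = R, cup_arc_fraction = p$cup_arc_fraction,
                          tip_enrichment = p$tip_enrichment,
                          base_enrichment = p$base_enrichment,
                          membrane_intensity = p$membrane_intensity,
                          background_level = p$background_level,
                          noise_sd = p$noise_sd, pixel_size = p$pixel_size,
                          cup_arc_length_um = 2 * alpha * R),
                     p$seed)
  list(image = img, contour = contour, ground_truth = gt)
}

#' Ground-truth record attached to every generated artifact
#'
#' @param generator_name label of the generator that produced the artifact.
#' @param parameter_record named list of the true parameter values.
#' @param seed the RNG seed used.
#' @return An object of class `"ground_truth"`.
#' @export
ground_truth <- function(generator_name, parameter_record, seed) {
  structure(list(generator_name = generator_name,
                 parameter_record = parameter_record,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> generator '%s' (seed %d)\n",
              x$generator_name, x$seed))
  for (nm in names(x$parameter_record)) {
    v <- x$parameter_record[[nm]]
    cat(sprintf("  %s: %s\n", nm, paste(signif(unlist(v), 5), collapse = ", ")))
  }
  invisible(x)
}
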