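#' Parameters for the chemotaxis track generator
#'
#' Biased correlated random walks: at every step the cell either heads
#' straight up the gradient (with probability `directional_bias`) or
#' turns from its previous heading by a Gaussian angle of sd `turn_sd`;
#' step lengths are Gaussian with mean `mean_speed * dt` and sd
#' `speed_sd * dt` (truncated at 0). `directional_bias = 1` gives
#' straight runs up the gradient; `directional_bias = 0` gives an
#' unbiased correlated walk.
#'
#' @param n_tracks number of tracks.
#' @param n_steps steps per track.
#' @param dt frame interval, minutes.
#' @param mean_speed mean instantaneous speed, micrometres per minute.
#' @param directional_bias probability of a gradient-directed step, `[0,1]`.
#' @param gradient_axis unit 2-vector of the gradient direction.
#' @param speed_sd sd of instantaneous speed, um/min (0 = constant speed).
#' @param turn_sd turning-angle sd of unbiased steps, radians.
#' @param seed integer RNG seed.
#' @return List of class `"track_params"`.
#' @export
track_params <- function(n_tracks = 10L, n_steps = 60L, dt = 0.5,
                         mean_speed = 10, directional_bias = 0.5,
                         gradient_axis = c(1, 0), speed_sd = 2,
                         turn_sd = 0.6, seed = 1L) {
  check_that(n_tracks >= 1 && n_steps >= 1, "need n_tracks, n_steps >= 1")
  check_that(dt > 0, "dt must be positive")
  check_that(mean_speed >= 0 && speed_sd >= 0, "speeds must be >= 0")
  check_that(directional_bias >= 0 && directional_bias <= 1,
             "directional_bias must lie in [0, 1]")
  check_unit_vector(gradient_axis)
  structure(list(n_tracks = as.integer(n_tracks),
                 n_steps = as.integer(n_steps), dt = dt,
                 mean_speed = mean_speed,
                 directional_bias = directional_bias,
                 gradient_axis = as.numeric(gradient_axis),
                 speed_sd = speed_sd, turn_sd = turn_sd,
                 seed = as.integer(seed)),
            class = "track_params")
}

#' Generate biased correlated random-walk tracks with ground truth
#'
#' @param params a [track_params()] object.
#' @return List with `tracks` (a `"track_set"`: list of [cell_track()]s
#'   plus the gradient axis) and `ground_truth`.
#' @export
generate_tracks <- function(params) {
  if (!inherits(params, "track_params")) {
    params <- do.call(track_params, as.list(params))
  }
  p <- params
  grad_angle <- atan2(p$gradient_axis[2], p$gradient_axis[1])
  tracks <- with_seed(p$seed, {
    lapply(seq_len(p$n_tracks), function(i) {
      heading <- stats::runif(1, -pi, pi)
      xy <- matrix(0, p$n_steps + 1L, 2)
      for (s in seq_len(p$n_steps)) {
        if (stats::runif(1) < p$directional_bias) {
          heading <- grad_angle
        } else if (p$turn_sd > 0) {
          heading <- heading + stats::rnorm(1, 0, p$turn_sd)
        }
        step <- max(stats::rnorm(1, p$mean_speed * p$dt, p$speed_sd * p$dt), 0)
        xy[s + 1L, ] <- xy[s, ] + step * c(cos(heading), sin(heading))
      }
      cell_track(track_id = sprintf("track%03d", i),
                 times = seq(0, by = p$dt, length.out = p$n_steps + 1L),
                 positions = xy, gradient_axis = p$gradient_axis)
    })
  })
  gt <- ground_truth("tracks",
                     list(mean_speed = p$mean_speed,
                          directional_bias = p$directional_bias,
                          n_tracks = p$n_tracks, dt = p$dt,
                          speed_sd = p$speed_sd, turn_sd = p$turn_sd),
                     p$seed)
  list(tracks = structure(list(tracks = tracks,
                               gradient_axis = p$gradient_axis),
                          class = "track_set"),
       ground_truth = gt)
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, gradient axis (%.2f, %.2f)\n",
              length(x$tracks), x$gradient_axis[1], x$gradient_axis[2]))
  invisible(x)
}

#' Parameters for the macropinosome spot-table generator
#'
#' Spot diameters are log-normal (positive and right-skewed, like
#' measured nascent-macropinosome diameters); spot counts per cell are
#' Poisson.
#'
#' @param n_cells number of cells (0 gives an empty table).
#' @param spots_per_cell_mean Poisson mean of spots per cell.
#' @param diameter_log_mean mean of log diameter (log-micrometres).
#' @param diameter_log_sd sd of log diameter (0 = degenerate, all spots
#'   identical).
#' @param seed integer RNG seed.
#' @return List of class `"spot_table_params"`.
#' @export
spot_table_params <- function(n_cells = 30L, spots_per_cell_mean = 3,
                              diameter_log_mean = log(1.2),
                              diameter_log_sd = 0.25, seed = 1L) {
  check_that(n_cells >= 0 && spots_per_cell_mean >= 0,
             "counts must be >= 0")
  check_that(diameter_log_sd >= 0, "diameter_log_sd must be >= 0")
  structure(list(n_cells = as.integer(n_cells),
                 spots_per_cell_mean = spots_per_cell_mean,
                 diameter_log_mean = diameter_log_mean,
                 diameter_log_sd = diameter_log_sd,
                 seed = as.integer(seed)),
            class = "spot_table_params")
}

#' Generate a macropinosome spot table with ground truth
#'
#' The ground truth stores the analytic mean sphere volume of the
#' diameter distribution: for log-normal diameters,
#' `E[V] = (pi/6) exp(3 mu + 9 sigma^2 / 2)`.
#'
#' @param params a [spot_table_params()] object.
#' @return List with `spots` (data.frame `cell_id`, `spot_id`,
#'   `diameter_um`), `cell_ids` (all generated cells, including those
#'   with zero spots) and `ground_truth`.
#' @export
generate_spot_table <- function(params) {
  if (!inherits(params, "spot_table_params")) {
    params <- do.call(spot_table_params, as.list(params))
  }
  p <- params
  cell_ids <- if (p$n_cells > 0) sprintf("cell%03d", seq_len(p$n_cells))
              else character()
  spots <- with_seed(p$seed, {
    rows <- lapply(seq_len(p$n_cells), function(i) {
      k <- stats::rpois(1, p$spots_per_cell_mean)
      if (k == 0) return(NULL)
      data.frame(cell_id = cell_ids[i], spot_id = seq_len(k),
                 diameter_um = stats::rlnorm(k, p$diameter_log_mean,
                                             p$diameter_log_sd),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(cell_id = character(), spot_id = integer(),
                        diameter_um = numeric())
    }
    out
  })
  true_mean_volume <- (pi / 6) * exp(3 * p$diameter_log_mean +
                                       4.5 * p$diameter_log_sd^2)
  gt <- ground_truth("spot_table",
                     list(n_cells = p$n_cells,
                          spots_per_cell_mean = p$spots_per_cell_mean,
                          diameter_log_mean = p$diameter_log_mean,
                          diameter_log_sd = p$diameter_log_sd,
                          true_mean_volume_um3 = true_mean_volume),
                     p$seed)
  list(spots = spots, cell_ids = cell_ids, ground_truth = gt)
}

#' Parameters for the bead/bacterium shape-image generator
#'
#' Rasterizes non-overlapping ellipses. `long_axis` and `aspect_ratio`
#' may be vectors (recycled over objects) to generate mixed populations,
#' e.g. spheres plus 2.6x-stretched beads.
#'
#' @param n_objects number of objects.
#' @param long_axis ellipse long axis (Feret diameter), micrometres.
#' @param aspect_ratio long axis / short axis, `>= 1`.
#' @param pixel_size micrometres per pixel.
#' @param random_orientation rotate each ellipse uniformly at random?
#' @param orientation fixed orientation(s) in radians, recycled over
#'   objects; used when `random_orientation = FALSE` (default 0).
#' @param image_size_um side length of the square field, micrometres;
#'   `NULL` (default) sizes the field to fit the requested objects.
#' @param seed integer RNG seed.
#' @return List of class `"shape_image_params"`.
#' @export
shape_image_params <- function(n_objects = 20L, long_axis = 3,
                               aspect_ratio = 1, pixel_size = 0.1,
                               random_orientation = TRUE, orientation = 0,
                               image_size_um = NULL, seed = 1L) {
  check_that(n_objects >= 1, "need n_objects >= 1")
  check_that(all(long_axis > 0), "long_axis must be positive")
  check_that(all(aspect_ratio >= 1), "aspect_ratio must be >= 1")
  check_that(pixel_size > 0, "pixel_size must be positive")
  structure(list(n_objects = as.integer(n_objects),
                 long_axis = long_axis, aspect_ratio = aspect_ratio,
                 pixel_size = pixel_size,
                 random_orientation = isTRUE(random_orientation),
                 orientation = orientation,
                 image_size_um = image_size_um,
                 seed = as.integer(seed)),
            class = "shape_image_params")
}

#' Generate a labeled mask of ellipses with ground truth
#'
#' Objects are placed by rejection sampling with a minimum
#' center-to-center separation; if a placement cannot be found within
#' the retry budget a packing error is raised. Ground truth stores each
#' object's axes, orientation and true class (`spherical` if its aspect
#' ratio is below `class_threshold`).
#'
#' @param params a [shape_image_params()] object.
#' @param class_threshold aspect ratio separating the true classes.
#' @return List with `mask` (integer label matrix), `ground_truth`
#'   (parameter record contains a per-object data.frame `objects`).
#' @export
generate_shape_image <- function(params, class_threshold = 1.5) {
  if (!inherits(params, "shape_image_params")) {
    params <- do.call(shape_image_params, as.list(params))
  }
  p <- params
  n <- p$n_objects
  a <- rep(p$long_axis, length.out = n)       # long axis, um
  ar <- rep(p$aspect_ratio, length.out = n)
  b <- a / ar                                  # short axis, um
  side_um <- if (is.null(p$image_size_um)) {
    cell_pitch <- max(a) * 1.2 + 2 * p$pixel_size
    ceiling(sqrt(n)) * cell_pitch + max(a)
  } else {
    p$image_size_um
  }
  check_that(side_um > max(a) + 2 * p$pixel_size,
             "field too small for the largest object",
             abort = abort_geometry)
  npx <- ceiling(side_um / p$pixel_size)
  min_sep <- max(a) * 1.02
  placement <- with_seed(p$seed, {
    centers <- matrix(NA_real_, n, 2)
    theta <- numeric(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        cand <- stats::runif(2, max(a) / 2 + p$pixel_size,
                             side_um - max(a) / 2 - p$pixel_size)
        if (i == 1 || all(sqrt(rowSums((centers[seq_len(i - 1), ,
                                                drop = FALSE] -
                                          matrix(cand, i - 1, 2,
                                                 byrow = TRUE))^2)) >=
                            min_sep)) {
          centers[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort_geometry("could not place ", n,
                       " objects without overlap (packing error)")
      }
      theta[i] <- if (p$random_orientation) stats::runif(1, 0, pi)
                  else rep(p$orientation, length.out = n)[i]
    }
    list(centers = centers, theta = theta)
  })
  mask <- matrix(0L, npx, npx)
  xc <- (seq_len(npx) - 0.5) * p$pixel_size
  for (i in seq_len(n)) {
    cx <- placement$centers[i, 1]; cy <- placement$centers[i, 2]
    th <- placement$theta[i]
    half <- a[i] / 2 + p$pixel_size
    cols <- which(xc >= cx - half & xc <= cx + half)
    rows <- which(xc >= cy - half & xc <= cy + half)
    X <- matrix(xc[cols], length(rows), length(cols), byrow = TRUE) - cx
    Y <- matrix(xc[rows], length(rows), length(cols)) - cy
    U <- X * cos(th) + Y * sin(th)
    V <- -X * sin(th) + Y * cos(th)
    inside <- (U / (a[i] / 2))^2 + (V / (b[i] / 2))^2 <= 1
    sub <- mask[rows, cols, drop = FALSE]
    sub[inside] <- i
    mask[rows, cols] <- sub
  }
  objects <- data.frame(object_id = seq_len(n), long_axis_um = a,
                        short_axis_um = b, aspect_ratio = ar,
                        orientation_rad = placement$theta,
                        true_class = ifelse(ar >= class_threshold,
                                            "ellipsoid", "spherical"),
                        stringsAsFactors = FALSE)
  gt <- ground_truth("shape_image",
                     list(pixel_size = p$pixel_size,
                          class_threshold = class_threshold,
                          objects = objects),
                     p$seed)
  list(mask = mask, ground_truth = gt)
}

#' Parameters for the GDP-production kinetics generator
#'
#' %GDP(t) follows `min(saturation_level, k t)` plus Gaussian noise,
#' clipped to `[0, 100]` - an initial linear hydrolysis regime that
#' saturates.
#'
#' @param n_points number of time points (>= 4).
#' @param dt sampling interval, minutes.
#' @param initial_rate `k`, %GDP per minute.
#' @param saturation_level plateau, percent in (0, 100].
#' @param noise_sd Gaussian noise sd, percentage points.
#' @param seed integer RNG seed.
#' @return List of class `"kinetics_params"`.
#' @export
kinetics_params <- function(n_points = 10L, dt = 3, initial_rate = 5,
                            saturation_level = 100, noise_sd = 0,
                            seed = 1L) {
  check_that(n_points >= 4, "n_points must be >= 4")
  check_that(dt > 0, "dt must be positive")
  check_that(initial_rate >= 0, "initial_rate must be >= 0")
  check_that(saturation_level > 0 && saturation_level <= 100,
             "saturation_level must lie in (0, 100]")
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(n_points = as.integer(n_points), dt = dt,
                 initial_rate = initial_rate,
                 saturation_level = saturation_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "kinetics_params")
}

#' Generate a %GDP time course with ground truth
#'
#' @param params a [kinetics_params()] object.
#' @param condition label carried into the series.
#' @return List with `series` (a [kinetics_series()]) and `ground_truth`.
#' @export
generate_kinetics <- function(params, condition = "condition") {
  if (!inherits(params, "kinetics_params")) {
    params <- do.call(kinetics_params, as.list(params))
  }
  p <- params
  t <- seq(0, by = p$dt, length.out = p$n_points)
  y <- pmin(p$saturation_level, p$initial_rate * t)
  if (p$noise_sd > 0) {
    y <- y + with_seed(p$seed, stats::rnorm(p$n_points, 0, p$noise_sd))
  }
  y <- pmin(pmax(y, 0), 100)
  gt <- ground_truth("kinetics",
                     list(initial_rate = p$initial_rate,
                          saturation_level = p$saturation_level,
                          dt = p$dt, noise_sd = p$noise_sd),
                     p$seed)
  list(series = kinetics_series(t, y, condition), ground_truth = gt)
}
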