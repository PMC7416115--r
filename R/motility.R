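#' Construct a cell track
#'
#' @param track_id label.
#' @param times time points, minutes, strictly increasing (irregular
#'   sampling allowed; gaps are simply longer segments).
#' @param positions n x 2 matrix of x/y coordinates, micrometres.
#' @param gradient_axis unit 2-vector pointing up the attractant gradient.
#' @return Object of class `"cell_track"`.
#' @export
cell_track <- function(track_id, times, positions, gradient_axis = c(1, 0)) {
  positions <- as.matrix(positions)
  check_that(length(times) >= 2 && nrow(positions) == length(times),
             "a track needs >= 2 time points with matching positions")
  check_that(all(is.finite(times)) && all(diff(times) > 0),
             "times must be finite and strictly increasing")
  check_that(all(is.finite(positions)), "positions must be finite")
  check_unit_vector(gradient_axis)
  structure(list(track_id = track_id, times = as.numeric(times),
                 positions = positions,
                 gradient_axis = as.numeric(gradient_axis)),
            class = "cell_track")
}

#' Track speed
#'
#' Total path distance divided by elapsed time.
#'
#' @param track a [cell_track()].
#' @return Speed, micrometres per minute.
#' @export
track_speed <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  dt <- track$times[length(track$times)] - track$times[1]
  check_that(dt > 0, "track duration must be positive")
  path_length(track$positions) / dt
}

path_length <- function(xy) {
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Chemotactic index
#'
#' Net displacement projected on the gradient axis divided by total path
#' length; 1 means perfectly directed motion up the gradient, negative
#' values motion away from it. By the triangle inequality the result is
#' always in `[-1, 1]`. For a stationary track (zero path length) the
#' index is undefined and `NA` is returned with a warning.
#'
#' @param track a [cell_track()].
#' @return Dimensionless index in `[-1, 1]`, or `NA` for a stationary
#'   track.
#' @export
chemotactic_index <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  path <- path_length(track$positions)
  if (path == 0) {
    warning("stationary track: chemotactic index undefined (NA)")
    return(NA_real_)
  }
  net <- track$positions[nrow(track$positions), ] - track$positions[1, ]
  sum(net * track$gradient_axis) / path
}

#' Cohort summary of track statistics
#'
#' @param tracks a `"track_set"` (see [generate_tracks()]) or a plain
#'   list of [cell_track()]s.
#' @return List of class `"track_summary"` with `per_track` (data.frame:
#'   `track_id`, `speed_um_min`, `chemotactic_index`) and `cohort`
#'   (mean, sd, SEM and n for both statistics; SEM is 0 for n = 1).
#' @export
cohort_summary <- function(tracks) {
  if (inherits(tracks, "track_set")) tracks <- tracks$tracks
  check_that(is.list(tracks) && length(tracks) >= 1,
             "need at least one track")
  stopifnot(all(vapply(tracks, inherits, TRUE, "cell_track")))
  per <- data.frame(
    track_id = vapply(tracks, function(t) as.character(t$track_id), ""),
    speed_um_min = vapply(tracks, track_speed, 0),
    chemotactic_index = vapply(tracks, chemotactic_index, 0),
    stringsAsFactors = FALSE)
  stat <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    s <- if (n > 1) stats::sd(x) else 0
    list(mean = mean(x), sd = s, sem = if (n > 1) s / sqrt(n) else 0, n = n)
  }
  structure(list(per_track = per,
                 cohort = list(speed = stat(per$speed_um_min),
                               ci = stat(per$chemotactic_index))),
            class = "track_summary")
}

#' @export
print.track_summary <- function(x, ...) {
  s <- x$cohort$speed; ci <- x$cohort$ci
  cat(sprintf("<track_summary> %d tracks\n", nrow(x$per_track)))
  cat(sprintf("  speed: %.2f +/- %.2f um/min (mean +/- SEM)\n", s$mean, s$sem))
  cat(sprintf("  chemotactic index: %.3f +/- %.3f\n", ci$mean, ci$sem))
  invisible(x)
}
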