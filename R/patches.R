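#' Detect signalling patches on a closed cell perimeter
#'
#' Finds contiguous runs of membrane signal above
#' `background mean + threshold_k * background sd` on arc-length samples
#' covering the full perimeter, with circular wrap-around (a run spanning
#' the arc-length origin is one patch). Runs separated by gaps shorter
#' than `merge_gap` are merged, and merged runs shorter than `min_arc`
#' are discarded. Patch boundaries are placed midway between the last
#' above-threshold and first below-threshold samples.
#'
#' @param s arc-length sample positions, micrometres, strictly increasing
#'   within `[0, perimeter)`.
#' @param intensity membrane intensity at each sample, a.u.
#' @param perimeter total perimeter, micrometres.
#' @param background_mean,background_sd background statistics, a.u.
#' @param threshold_k threshold in background sds above the mean.
#' @param min_arc minimum patch arc length, micrometres.
#' @param merge_gap gaps shorter than this are bridged, micrometres.
#' @param cell_id label carried into outputs.
#' @return An object of class `"patch_set"`: `perimeter`, `arcs` (matrix
#'   with columns `s_start`, `s_end`; `s_end` may exceed the perimeter
#'   for the single patch that wraps the origin), `cell_id`.
#' @export
detect_patches <- function(s, intensity, perimeter,
                           background_mean, background_sd,
                           threshold_k = 2, min_arc = 1.0, merge_gap = 0.5,
                           cell_id = "cell") {
  check_that(length(s) == length(intensity) && length(s) >= 8,
             "need >= 8 perimeter samples")
  check_that(all(diff(s) > 0) && s[1] >= 0 && s[length(s)] < perimeter,
             "sample positions must be strictly increasing in [0, perimeter)")
  check_that(perimeter > 0 && background_sd >= 0,
             "invalid perimeter or background sd")
  level <- background_mean + threshold_k * background_sd
  above <- intensity > level
  n <- length(s)
  if (!any(above)) {
    return(patch_set(perimeter, matrix(numeric(0), 0, 2), cell_id))
  }
  if (all(above)) {
    return(patch_set(perimeter, matrix(c(0, perimeter), 1, 2), cell_id))
  }
  # Rotate so sample 1 is below threshold; then runs never cross the
  # rotated origin and wrap-around falls out naturally.
  first_below <- which(!above)[1]
  rot <- c(seq(first_below, n), seq_len(first_below - 1L))
  ab <- above[rot]
  # Sample positions on the unrolled (rotated) axis.
  srot <- s[rot]
  srot[srot < s[first_below]] <- srot[srot < s[first_below]] + perimeter
  runs <- rle(ab)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  arcs <- NULL
  for (j in which(runs$values)) {
    i1 <- starts[j]; i2 <- ends[j]
    # boundary midway to the neighbouring below-threshold samples
    s_start <- (srot[i1 - 1L] + srot[i1]) / 2        # i1 >= 2 by rotation
    s_end <- if (i2 < n) (srot[i2] + srot[i2 + 1L]) / 2
             else (srot[n] + (srot[1] + perimeter)) / 2
    arcs <- rbind(arcs, c(s_start, s_end))
  }
  # Merge runs separated by short gaps, including the circular gap
  # between the last and first run across the rotated origin.
  if (nrow(arcs) > 1) {
    merged <- arcs[1, , drop = FALSE]
    for (i in 2:nrow(arcs)) {
      gap <- arcs[i, 1] - merged[nrow(merged), 2]
      if (gap < merge_gap - 1e-9) {
        merged[nrow(merged), 2] <- arcs[i, 2]
      } else {
        merged <- rbind(merged, arcs[i, , drop = FALSE])
      }
    }
    if (nrow(merged) > 1) {
      wrap_gap <- (merged[1, 1] + perimeter) - merged[nrow(merged), 2]
      if (wrap_gap < merge_gap - 1e-9) {
        merged[nrow(merged), 2] <- merged[1, 2] + perimeter
        merged <- merged[-1, , drop = FALSE]
      }
    }
    arcs <- merged
  }
  # A single remaining arc whose own circular gap is below merge_gap
  # closes into a full-perimeter patch.
  if (nrow(arcs) == 1 &&
      (arcs[1, 1] + perimeter) - arcs[1, 2] < merge_gap - 1e-9) {
    arcs <- matrix(c(0, perimeter), 1, 2)
  }
  arcs <- arcs[arcs[, 2] - arcs[, 1] >= min_arc - 1e-9, , drop = FALSE]
  # Map back to [0, perimeter): wrapped patches keep s_end > perimeter.
  if (nrow(arcs) > 0) {
    shift <- arcs[, 1] >= perimeter
    arcs[shift, ] <- arcs[shift, ] - perimeter
    arcs <- arcs[order(arcs[, 1]), , drop = FALSE]
  }
  patch_set(perimeter, arcs, cell_id)
}

#' Construct a patch set
#'
#' @param perimeter cell perimeter, micrometres.
#' @param arcs numeric matrix with columns `s_start`, `s_end` in
#'   micrometres; for a patch wrapping the arc-length origin `s_end` may
#'   exceed `perimeter` (unwrapped convention).
#' @param cell_id label.
#' @return Object of class `"patch_set"`.
#' @export
patch_set <- function(perimeter, arcs, cell_id = "cell") {
  arcs <- matrix(as.numeric(arcs), ncol = 2,
                 dimnames = list(NULL, c("s_start", "s_end")))
  check_that(perimeter > 0, "perimeter must be positive")
  if (nrow(arcs) > 0) {
    check_that(all(arcs[, 2] > arcs[, 1]),
               "every arc needs s_end > s_start (unwrapped)")
    check_that(all(arcs[, 1] >= 0 & arcs[, 1] < perimeter),
               "arc starts must lie in [0, perimeter)")
    check_that(sum(arcs[, 2] - arcs[, 1]) <= perimeter + 1e-9,
               "total patch length exceeds the perimeter")
  }
  structure(list(perimeter = perimeter, arcs = arcs, cell_id = cell_id),
            class = "patch_set")
}

#' Patch morphometry summary
#'
#' @param patches a [patch_set()].
#' @return List with `sizes` (arc lengths, um), `count`, and
#'   `perimeter_fraction` (total patch length / perimeter, in `[0, 1]`).
#' @export
patch_stats <- function(patches) {
  stopifnot(inherits(patches, "patch_set"))
  sizes <- as.numeric(patches$arcs[, 2] - patches$arcs[, 1])
  list(sizes = sizes, count = length(sizes),
       perimeter_fraction = min(sum(sizes) / patches$perimeter, 1))
}

#' @export
print.patch_set <- function(x, ...) {
  st <- patch_stats(x)
  cat(sprintf("<patch_set> %s: %d patch(es) on %.2f um perimeter (phi = %.1f%%)\n",
              x$cell_id, st$count, x$perimeter, 100 * st$perimeter_fraction))
  invisible(x)
}
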