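#' Cell contour with cup and reference annotations
#'
#' An ordered, closed cell outline in micrometres, together with the
#' anchor information the profile extractor needs: the indices of the two
#' cup tips and the index range of a non-protrusive reference arc on the
#' opposite side of the cell. The tip-to-tip path running *forward* from
#' `tip_indices[1]` to `tip_indices[2]` is the cup interior membrane.
#'
#' @param points numeric matrix (n x 2) of x/y coordinates in micrometres,
#'   ordered along the outline; the outline is treated as closed (last
#'   point connects back to the first).
#' @param tip_indices integer vector of length 2, indices into `points`
#'   marking the two protrusive cup tips.
#' @param reference_arc integer vector of length 2, `(start, end)` indices
#'   of the non-protrusive reference arc.
#' @param closed logical; kept for file round-trips, must be `TRUE`.
#'
#' @return An object of class `"cup_contour"`: a list with elements
#'   `points`, `arc_length` (cumulative arc length per point, starting at
#'   0), `tip_indices`, `reference_arc`, `closed`.
#' @export
cup_contour <- function(points, tip_indices, reference_arc, closed = TRUE) {
  points <- as.matrix(points)
  check_that(is.numeric(points) && ncol(points) == 2 && nrow(points) >= 3,
             "contour needs an n x 2 numeric matrix with >= 3 points")
  check_that(all(is.finite(points)), "contour coordinates must be finite")
  d <- sqrt(rowSums((points - points[c(nrow(points), 1:(nrow(points) - 1)), ])^2))
  d[1] <- 0
  arc <- cumsum(d)
  check_that(all(diff(arc) > 0), "arc length must be strictly increasing ",
             "(duplicate consecutive contour points?)")
  tip_indices <- as.integer(tip_indices)
  check_that(length(tip_indices) == 2 && !anyNA(tip_indices) &&
               tip_indices[1] != tip_indices[2] &&
               all(tip_indices >= 1 & tip_indices <= nrow(points)),
             "tip_indices must be two distinct indices into the contour")
  reference_arc <- as.integer(reference_arc)
  check_that(length(reference_arc) == 2 && !anyNA(reference_arc) &&
               all(reference_arc >= 1 & reference_arc <= nrow(points)) &&
               reference_arc[1] < reference_arc[2],
             "reference_arc must be a valid (start, end) index pair")
  cup <- seq(tip_indices[1], tip_indices[2])
  check_that(!any(seq(reference_arc[1], reference_arc[2]) %in% cup),
             "reference arc must be disjoint from the cup (tip-to-tip) arc")
  structure(list(points = points, arc_length = arc,
                 tip_indices = tip_indices, reference_arc = reference_arc,
                 closed = isTRUE(closed)),
            class = "cup_contour")
}

#' @export
print.cup_contour <- function(x, ...) {
  per <- x$arc_length[length(x$arc_length)] +
    sqrt(sum((x$points[1, ] - x$points[nrow(x$points), ])^2))
  cat(sprintf("<cup_contour> %d points, perimeter %.2f um\n",
              nrow(x$points), per))
  cat(sprintf("  tips at indices %d, %d; reference arc [%d, %d]\n",
              x$tip_indices[1], x$tip_indices[2],
              x$reference_arc[1], x$reference_arc[2]))
  invisible(x)
}

contour_perimeter <- function(contour) {
  n <- nrow(contour$points)
  contour$arc_length[n] +
    sqrt(sum((contour$points[1, ] - contour$points[n, ])^2))
}

# Resample a stretch of contour (from index i1 to i2, forward) at a fixed
# spacing, returning positions (arc length from the start of the stretch)
# and interpolated xy coordinates.
resample_contour_path <- function(contour, i1, i2, spacing) {
  idx <- seq(i1, i2)
  pts <- contour$points[idx, , drop = FALSE]
  s <- contour$arc_length[idx] - contour$arc_length[i1]
  total <- s[length(s)]
  pos <- seq(0, total, by = spacing)
  if (pos[length(pos)] < total) pos <- c(pos, total)
  x <- stats::approx(s, pts[, 1], xout = pos)$y
  y <- stats::approx(s, pts[, 2], xout = pos)$y
  list(pos = pos, xy = cbind(x, y))
}

# Unit tangents/normals along a sampled path; normals point away from
# `centroid` (the cell body), i.e. toward the extracellular side.
path_normals <- function(xy, centroid) {
  n <- nrow(xy)
  nxt <- pmin(seq_len(n) + 1L, n)
  prv <- pmax(seq_len(n) - 1L, 1L)
  tx <- xy[nxt, 1] - xy[prv, 1]
  ty <- xy[nxt, 2] - xy[prv, 2]
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  nx <- -ty / len
  ny <- tx / len
  flip <- (nx * (xy[, 1] - centroid[1]) + ny * (xy[, 2] - centroid[2])) < 0
  nx[flip] <- -nx[flip]
  ny[flip] <- -ny[flip]
  cbind(nx, ny)
}
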