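#' Shape object from a binary pixel mask
#'
#' Wraps one segmented object (an engulfed bead or bacterium) and derives
#' its caliper metrics: the Feret (maximum caliper) diameter used as the
#' long axis, the minimum caliper width, and their ratio.
#'
#' @param mask logical or 0/1 matrix; must contain a non-empty connected
#'   object.
#' @param pixel_size micrometres per pixel.
#' @param object_id label.
#' @return Object of class `"shape_object"` with `pixels` (n x 2 matrix
#'   of row/col indices), `pixel_size`, `feret`, `min_caliper`, `aspect`
#'   (all micrometres / dimensionless). Single-pixel objects get
#'   `feret = 0` and `aspect = NA` (degenerate, flagged).
#' @export
shape_object <- function(mask, pixel_size = 1, object_id = "obj") {
  check_that(pixel_size > 0, "pixel_size must be positive")
  mask <- mask != 0
  px <- which(mask, arr.ind = TRUE)
  check_that(nrow(px) > 0, "mask is empty")
  bnd <- boundary_pixels(mask, px)
  # caliper metrics from convex hull of boundary-pixel centers
  xy <- cbind(bnd[, 2] - 0.5, bnd[, 1] - 0.5) * pixel_size
  if (nrow(xy) == 1) {
    feret <- 0; minc <- 0; aspect <- NA_real_
  } else {
    hull <- xy[unique(grDevices::chull(xy)), , drop = FALSE]
    feret <- max_pairwise_distance(hull)
    minc <- min_caliper_width(hull)
    aspect <- if (minc > 0) feret / minc else NA_real_
  }
  structure(list(pixels = px, pixel_size = pixel_size, object_id = object_id,
                 feret = feret, min_caliper = minc, aspect = aspect),
            class = "shape_object")
}

boundary_pixels <- function(mask, px = which(mask, arr.ind = TRUE)) {
  nr <- nrow(mask); nc <- ncol(mask)
  at <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- logical(length(r))
    out[ok] <- mask[cbind(r[ok], c[ok])]
    out
  }
  interior <- at(px[, 1] - 1L, px[, 2]) & at(px[, 1] + 1L, px[, 2]) &
    at(px[, 1], px[, 2] - 1L) & at(px[, 1], px[, 2] + 1L)
  px[!interior, , drop = FALSE]
}

max_pairwise_distance <- function(xy) {
  d <- as.matrix(stats::dist(xy))
  max(d)
}

# Minimum caliper width of a convex polygon: for each hull edge, the
# farthest vertex distance from the edge's supporting line; the minimum
# over edges is the min caliper (rotating-calipers identity).
min_caliper_width <- function(hull) {
  n <- nrow(hull)
  if (n == 2) return(0)
  widths <- numeric(n)
  for (i in seq_len(n)) {
    p1 <- hull[i, ]
    p2 <- hull[if (i == n) 1L else i + 1L, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len == 0) { widths[i] <- Inf; next }
    nrm <- c(-e[2], e[1]) / len
    widths[i] <- max(abs((hull[, 1] - p1[1]) * nrm[1] +
                           (hull[, 2] - p1[2]) * nrm[2]))
  }
  min(widths)
}

#' Feret (maximum caliper) diameter of an object
#'
#' Maximum pairwise distance between convex-hull vertices of the
#' object's boundary-pixel centers, scaled to micrometres. This is the
#' long-axis measure used for bacteria and beads.
#'
#' @param obj a [shape_object()], or a binary matrix (then `pixel_size`
#'   is used).
#' @param pixel_size micrometres per pixel (matrix input only).
#' @return Feret diameter, micrometres; 0 for a single-pixel object.
#' @export
feret_diameter <- function(obj, pixel_size = 1) {
  if (is.matrix(obj) && !inherits(obj, "shape_object")) {
    obj <- shape_object(obj, pixel_size)
  }
  stopifnot(inherits(obj, "shape_object"))
  obj$feret
}

#' Classify an object as spherical or ellipsoid
#'
#' Objects with caliper aspect ratio (`feret / min_caliper`) at or above
#' `aspect_threshold` are called ellipsoid, otherwise spherical. The
#' boundary sits between the aspect ~1 (spheres) and ~2.6 (stretched
#' bead) populations; classification of degenerate single-pixel objects
#' is refused.
#'
#' @param obj a [shape_object()].
#' @param aspect_threshold dimensionless class boundary (default 1.5).
#' @return `"spherical"` or `"ellipsoid"`.
#' @export
classify_shape <- function(obj, aspect_threshold = 1.5) {
  stopifnot(inherits(obj, "shape_object"))
  check_that(aspect_threshold > 1, "aspect_threshold must exceed 1")
  if (is.na(obj$aspect)) {
    abort_validation("degenerate (single-pixel) object: classification refused")
  }
  if (obj$aspect >= aspect_threshold) "ellipsoid" else "spherical"
}

#' Shape metrics for every object in a labeled mask
#'
#' @param label_mask integer matrix; 0 = background, positive integers
#'   label objects.
#' @param pixel_size micrometres per pixel.
#' @param aspect_threshold passed to [classify_shape()].
#' @return data.frame with `object_id`, `feret_um`, `min_caliper_um`,
#'   `aspect`, `shape_class`.
#' @export
shape_metrics <- function(label_mask, pixel_size = 1, aspect_threshold = 1.5) {
  labs <- sort(setdiff(unique(as.vector(label_mask)), 0))
  check_that(length(labs) > 0, "label mask contains no objects")
  rows <- lapply(labs, function(l) {
    obj <- shape_object(label_mask == l, pixel_size, object_id = l)
    data.frame(object_id = l, feret_um = obj$feret,
               min_caliper_um = obj$min_caliper, aspect = obj$aspect,
               shape_class = classify_shape(obj, aspect_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-cell shape-resolved bead counts
#'
#' @param cells named list; each element is a character vector of shape
#'   classes (`"spherical"` / `"ellipsoid"`) for the beads engulfed by
#'   one cell (may be empty).
#' @return List with `per_cell` (data.frame: `cell_id`, `n_spherical`,
#'   `n_ellipsoid`), `mean_spherical`, `mean_ellipsoid`, and
#'   `uptake_ratio` (mean ellipsoid count / mean spherical count; `NA`
#'   when no spherical beads were engulfed at all).
#' @export
bead_counts <- function(cells) {
  check_that(is.list(cells), "cells must be a list of class vectors")
  ids <- names(cells)
  if (is.null(ids)) ids <- as.character(seq_along(cells))
  per <- data.frame(
    cell_id = ids,
    n_spherical = vapply(cells, function(x) sum(x == "spherical"), 0L),
    n_ellipsoid = vapply(cells, function(x) sum(x == "ellipsoid"), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  ms <- if (nrow(per)) mean(per$n_spherical) else 0
  me <- if (nrow(per)) mean(per$n_ellipsoid) else 0
  list(per_cell = per, mean_spherical = ms, mean_ellipsoid = me,
       uptake_ratio = if (ms > 0) me / ms else NA_real_)
}

#' @export
print.shape_object <- function(x, ...) {
  cat(sprintf("<shape_object> %s: %d px, feret %.2f um, aspect %s\n",
              x$object_id, nrow(x$pixels), x$feret,
              if (is.na(x$aspect)) "NA" else sprintf("%.2f", x$aspect)))
  invisible(x)
}
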