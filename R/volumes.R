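#' Sphere volume from a maximum diameter
#'
#' Macropinosome volume estimated from the measured maximum diameter,
#' assuming a spherical vesicle: `V = (pi/6) d^3`.
#'
#' @param d diameter(s), micrometres; must be positive.
#' @return Volume(s), cubic micrometres.
#' @export
sphere_volume <- function(d) {
  check_that(is.numeric(d) && all(is.finite(d)) && all(d > 0),
             "diameters must be finite and positive")
  (pi / 6) * d^3
}

#' Per-cell macropinosome volumetry
#'
#' From a spot table (one row per macropinosome, with its maximum
#' diameter), computes per-cell mean vesicle volume and spot count, and
#' cohort mean +/- SEM across cells. Cells listed with zero spots
#' contribute a count of 0 and an `NA` volume; they are excluded from
#' the cohort volume mean and flagged in the output.
#'
#' @param spots data.frame with columns `cell_id`, `spot_id`,
#'   `diameter_um` (positive; `(cell_id, spot_id)` unique).
#' @param all_cells optional vector of cell ids to report (so cells with
#'   no spots appear with count 0).
#' @return List with `per_cell` (data.frame: `cell_id`, `n_spots`,
#'   `mean_volume_um3`) and `cohort` (list: `mean_volume_um3`,
#'   `sem_volume_um3`, `mean_count`, `sem_count`, `n_cells`,
#'   `n_cells_no_spots`).
#' @export
macropinosome_stats <- function(spots, all_cells = NULL) {
  check_that(is.data.frame(spots) &&
               all(c("cell_id", "spot_id", "diameter_um") %in% names(spots)),
             "spots must have columns cell_id, spot_id, diameter_um")
  if (nrow(spots) > 0) {
    check_that(all(spots$diameter_um > 0), "diameters must be positive")
    check_that(!anyDuplicated(spots[, c("cell_id", "spot_id")]),
               "(cell_id, spot_id) pairs must be unique")
  }
  ids <- unique(c(as.character(spots$cell_id), as.character(all_cells)))
  if (length(ids) == 0) {
    return(list(per_cell = data.frame(cell_id = character(),
                                      n_spots = integer(),
                                      mean_volume_um3 = numeric()),
                cohort = list(mean_volume_um3 = NA_real_,
                              sem_volume_um3 = NA_real_,
                              mean_count = NA_real_, sem_count = NA_real_,
                              n_cells = 0L, n_cells_no_spots = 0L)))
  }
  per <- do.call(rbind, lapply(ids, function(id) {
    d <- spots$diameter_um[as.character(spots$cell_id) == id]
    data.frame(cell_id = id, n_spots = length(d),
               mean_volume_um3 = if (length(d)) mean(sphere_volume(d))
                                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  vol <- per$mean_volume_um3[!is.na(per$mean_volume_um3)]
  list(per_cell = per,
       cohort = list(mean_volume_um3 = if (length(vol)) mean(vol) else NA_real_,
                     sem_volume_um3 = if (length(vol)) sem(vol) else NA_real_,
                     mean_count = mean(per$n_spots),
                     sem_count = sem(per$n_spots),
                     n_cells = nrow(per),
                     n_cells_no_spots = sum(per$n_spots == 0)))
}
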