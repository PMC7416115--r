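## File I/O: TIFF images, CSV tables, JSON ground truth / summaries,
## YAML configuration. All numeric CSV columns are written with a fixed
## "%.6f" decimal format so repeated runs are byte-identical.

#' Write a multi-channel image as a multi-page TIFF
#'
#' One page per channel, 16-bit; intensities are rounded to integer
#' counts (values must lie in `[0, 65535]`).
#'
#' @param image numeric array (rows x cols x channels) or matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  check_that(all(image >= 0) && all(image <= 65535),
             "intensities must lie in [0, 65535] for 16-bit storage")
  pages <- lapply(seq_len(dim(image)[3]),
                  function(k) round(image[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a channel array
#'
#' @param path TIFF file written by [write_image_tiff()] (or any
#'   multi-page grayscale TIFF).
#' @param n_channels expected channel count, or `NULL` to accept any.
#' @return Numeric array (rows x cols x channels), intensities in counts.
#' @export
read_image_tiff <- function(path, n_channels = NULL) {
  check_that(file.exists(path), "file not found: ", path,
             abort = abort_validation)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(n_channels) && length(pages) < n_channels) {
    abort_validation("TIFF '", path, "' has ", length(pages),
                     " page(s), expected ", n_channels, " channels")
  }
  pages <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    round(pg * 65535)
  })
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

write_table_fixed <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- fmt_num(out[[j]])
    }
  }
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE, eol = "\n")
  invisible(path)
}

read_table_checked <- function(path, required) {
  check_that(file.exists(path), "file not found: ", path,
             abort = abort_validation)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_validation("malformed CSV '", path, "': missing column(s) ",
                     paste(missing, collapse = ", "))
  }
  df
}

#' Write / read a cell contour as CSV plus anchors sidecar
#'
#' The contour points go to `<path>` as `x_um,y_um`; the tip indices,
#' reference arc and closed flag go to a JSON sidecar `<path>.json`.
#'
#' @param contour a [cup_contour()].
#' @param path CSV path.
#' @return `path`, invisibly (writer); a [cup_contour()] (reader).
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(inherits(contour, "cup_contour"))
  write_table_fixed(data.frame(x_um = contour$points[, 1],
                               y_um = contour$points[, 2]), path)
  jsonlite::write_json(list(tip_indices = contour$tip_indices,
                            reference_arc = contour$reference_arc,
                            closed = contour$closed),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- read_table_checked(path, c("x_um", "y_um"))
  side <- paste0(path, ".json")
  check_that(file.exists(side), "anchors sidecar not found: ", side,
             abort = abort_validation)
  anchors <- jsonlite::read_json(side, simplifyVector = TRUE)
  cup_contour(cbind(df$x_um, df$y_um),
              tip_indices = anchors$tip_indices,
              reference_arc = anchors$reference_arc,
              closed = isTRUE(all(anchors$closed)))
}

#' Write / read chemotaxis tracks as CSV
#'
#' Columns `track_id, t_min, x_um, y_um`. On reading, each track's
#' timestamps are checked to be strictly increasing; violations raise a
#' validation error naming the track.
#'
#' @param tracks a `"track_set"` or list of [cell_track()]s.
#' @param path CSV path.
#' @param gradient_axis unit 2-vector used when reading (the gradient is
#'   experiment configuration, never inferred from data).
#' @return `path` invisibly (writer); a `"track_set"` (reader).
#' @export
write_tracks_csv <- function(tracks, path) {
  if (inherits(tracks, "track_set")) tracks <- tracks$tracks
  rows <- do.call(rbind, lapply(tracks, function(t) {
    data.frame(track_id = t$track_id, t_min = t$times,
               x_um = t$positions[, 1], y_um = t$positions[, 2],
               stringsAsFactors = FALSE)
  }))
  write_table_fixed(rows, path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path, gradient_axis = c(1, 0)) {
  df <- read_table_checked(path, c("track_id", "t_min", "x_um", "y_um"))
  check_unit_vector(gradient_axis)
  ids <- unique(df$track_id)
  tracks <- lapply(ids, function(id) {
    sub <- df[df$track_id == id, ]
    if (any(diff(sub$t_min) <= 0)) {
      abort_validation("track '", id,
                       "': timestamps not strictly increasing")
    }
    cell_track(id, sub$t_min, cbind(sub$x_um, sub$y_um), gradient_axis)
  })
  structure(list(tracks = tracks, gradient_axis = gradient_axis),
            class = "track_set")
}

#' Write / read a macropinosome spot table as CSV
#'
#' Columns `cell_id, spot_id, diameter_um`; diameters must be positive
#' and `(cell_id, spot_id)` unique.
#'
#' @param spots data.frame as produced by [generate_spot_table()].
#' @param path CSV path.
#' @return `path` invisibly (writer); the validated data.frame (reader).
#' @export
write_spots_csv <- function(spots, path) {
  write_table_fixed(spots[, c("cell_id", "spot_id", "diameter_um")], path)
}

#' @rdname write_spots_csv
#' @export
read_spots_csv <- function(path) {
  df <- read_table_checked(path, c("cell_id", "spot_id", "diameter_um"))
  bad <- which(!is.finite(df$diameter_um) | df$diameter_um <= 0)
  if (length(bad)) {
    abort_validation("spot table '", path, "': non-positive diameter at row ",
                     bad[1], " (cell ", df$cell_id[bad[1]], ")")
  }
  if (anyDuplicated(df[, c("cell_id", "spot_id")])) {
    abort_validation("spot table '", path,
                     "': duplicated (cell_id, spot_id)")
  }
  df
}

#' Write / read a %GDP kinetics table as CSV
#'
#' Columns `t_min, gdp_percent, condition`; one [kinetics_series()] per
#' condition on reading.
#'
#' @param series_list list of [kinetics_series()] objects.
#' @param path CSV path.
#' @return `path` invisibly (writer); named list of series (reader).
#' @export
write_kinetics_csv <- function(series_list, path) {
  if (inherits(series_list, "kinetics_series")) {
    series_list <- list(series_list)
  }
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(t_min = s$times, gdp_percent = s$gdp_percent,
               condition = s$condition, stringsAsFactors = FALSE)
  }))
  write_table_fixed(rows, path)
}

#' @rdname write_kinetics_csv
#' @export
read_kinetics_csv <- function(path) {
  df <- read_table_checked(path, c("t_min", "gdp_percent", "condition"))
  conds <- unique(df$condition)
  out <- lapply(conds, function(cd) {
    sub <- df[df$condition == cd, ]
    kinetics_series(sub$t_min, sub$gdp_percent, cd)
  })
  names(out) <- conds
  out
}

#' Write / read a two-channel profile pair as CSV plus sidecar
#'
#' Columns `position_um, intensity_A, intensity_B`; per-channel
#' backgrounds and reference intensities go to a JSON sidecar
#' `<path>.json`.
#'
#' @param pair list with `profile_A`, `profile_B` ([linescan_profile()]s).
#' @param path CSV path.
#' @return `path` invisibly (writer); a pair list (reader).
#' @export
write_profile_pair_csv <- function(pair, path) {
  a <- pair$profile_A; b <- pair$profile_B
  write_table_fixed(data.frame(position_um = a$positions,
                               intensity_A = a$intensities,
                               intensity_B = b$intensities), path)
  jsonlite::write_json(list(background_A = a$background,
                            background_B = b$background,
                            reference_A = a$reference_intensity,
                            reference_B = b$reference_intensity),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_pair_csv
#' @export
read_profile_pair_csv <- function(path) {
  df <- read_table_checked(path, c("position_um", "intensity_A",
                                   "intensity_B"))
  side <- paste0(path, ".json")
  check_that(file.exists(side), "background sidecar not found: ", side,
             abort = abort_validation)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  list(profile_A = linescan_profile(df$position_um, df$intensity_A, "A",
                                    meta$background_A, meta$reference_A),
       profile_B = linescan_profile(df$position_um, df$intensity_B, "B",
                                    meta$background_B, meta$reference_B))
}

#' Write / read a ground-truth record as JSON
#'
#' @param gt a [ground_truth()] object.
#' @param path JSON path.
#' @return `path` invisibly (writer); a [ground_truth()] (reader).
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ground_truth(x$generator_name, x$parameter_record, x$seed)
}

#' Pipeline configuration
#'
#' Bundles the tunable constants every stage consumes, with validation.
#' A YAML file with any subset of the fields can be loaded with
#' [read_config()]; unspecified fields keep their defaults.
#'
#' @param pixel_size micrometres per pixel.
#' @param threshold_k patch threshold, background sds above the mean.
#' @param aspect_threshold spherical/ellipsoid class boundary.
#' @param edge_threshold half-max fraction for edge detection/offset.
#' @param tip_fraction tip segment fraction for [tip_enrichment()].
#' @param n_grid fixed resampling grid length.
#' @param gradient_axis unit 2-vector of the chemoattractant gradient.
#' @param seed integer RNG seed for generators.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(pixel_size = 0.1, threshold_k = 2,
                            aspect_threshold = 1.5, edge_threshold = 0.5,
                            tip_fraction = 0.1, n_grid = 1000L,
                            gradient_axis = c(1, 0), seed = 1L) {
  check_that(pixel_size > 0, "pixel_size must be positive")
  check_that(n_grid >= 2, "n_grid must be >= 2")
  check_that(tip_fraction > 0 && tip_fraction <= 0.5,
             "tip_fraction must lie in (0, 0.5]")
  check_that(edge_threshold > 0 && edge_threshold < 1,
             "edge_threshold must lie in (0, 1)")
  check_that(aspect_threshold > 1, "aspect_threshold must exceed 1")
  check_unit_vector(gradient_axis)
  structure(list(pixel_size = pixel_size, threshold_k = threshold_k,
                 aspect_threshold = aspect_threshold,
                 edge_threshold = edge_threshold,
                 tip_fraction = tip_fraction, n_grid = as.integer(n_grid),
                 gradient_axis = as.numeric(gradient_axis),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with configuration fields.
#' @export
read_config <- function(path) {
  check_that(file.exists(path), "config file not found: ", path,
             abort = abort_validation)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_validation("unknown config field(s): ",
                     paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Write a stage result bundle with provenance
#'
#' Writes each table as fixed-format CSV, the cohort summary as JSON,
#' and a provenance record (config hash, seed, package version) so a run
#' can be reproduced exactly. Re-running with the same inputs, config
#' and seed yields byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param stage stage name, used as file prefix.
#' @param tables named list of data.frames.
#' @param summary list of cohort summary values.
#' @param config a [pipeline_config()].
#' @return The directory, invisibly.
#' @export
write_result_bundle <- function(dir, stage, tables = list(),
                                summary = list(),
                                config = pipeline_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    write_table_fixed(tables[[nm]],
                      file.path(dir, sprintf("%s_%s.csv", stage, nm)))
  }
  cfg_file <- file.path(dir, sprintf("%s_config.yaml", stage))
  yaml::write_yaml(unclass(config), cfg_file)
  prov <- list(stage = stage,
               config_md5 = unname(tools::md5sum(cfg_file)),
               seed = config$seed,
               package_version =
                 as.character(utils::packageVersion("engulfquant")))
  jsonlite::write_json(summary, file.path(dir, sprintf("%s_summary.json",
                                                       stage)),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  jsonlite::write_json(prov, file.path(dir, sprintf("%s_provenance.json",
                                                    stage)),
                       auto_unbox = TRUE)
  invisible(dir)
}
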