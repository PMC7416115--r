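#' Parameters for the two-channel profile-pair generator
#'
#' Emulates paired linescans drawn from the center of a cup outward past
#' the rim: channel A (active Ras probe) is a sigmoidal step from its
#' interior plateau down to background, centered at `edge_position`;
#' channel B (active Rac probe) has the same form but its edge sits at
#' `edge_position + channel_offset`, so positive offsets mean Rac
#' activity extends beyond the Ras patch edge.
#'
#' @param profile_length total profile length, micrometres.
#' @param sample_spacing sample spacing, micrometres.
#' @param edge_position position of the Ras half-max edge, micrometres.
#' @param channel_offset Rac edge minus Ras edge, micrometres (~0-2 um).
#' @param plateau_A,plateau_B interior plateau intensities, a.u.
#' @param background_A,background_B extracellular backgrounds, a.u.
#' @param edge_softness logistic width of the edge, micrometres; 0 gives
#'   an exact step.
#' @param noise_sd additive Gaussian noise sd, a.u.
#' @param seed integer RNG seed.
#' @return A list of class `"profile_pair_params"`.
#' @export
profile_pair_params <- function(profile_length = 8, sample_spacing = 0.1,
                                edge_position = 5, channel_offset = 0,
                                plateau_A = 500, plateau_B = 500,
                                background_A = 50, background_B = 50,
                                edge_softness = 0.3, noise_sd = 0,
                                seed = 1L) {
  check_that(sample_spacing > 0, "sample_spacing must be positive")
  check_that(edge_position > 0 && edge_position < profile_length,
             "edge_position must lie strictly inside the profile")
  check_that(edge_softness >= 0, "edge_softness must be >= 0")
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  b_edge <- edge_position + channel_offset
  check_that(b_edge > 0 && b_edge < profile_length,
             "edge_position + channel_offset falls outside the profile",
             abort = abort_geometry)
  check_that(plateau_A > background_A && plateau_B > background_B,
             "plateaus must exceed their backgrounds")
  structure(list(profile_length = profile_length,
                 sample_spacing = sample_spacing,
                 edge_position = edge_position,
                 channel_offset = channel_offset,
                 plateau_A = plateau_A, plateau_B = plateau_B,
                 background_A = background_A, background_B = background_B,
                 edge_softness = edge_softness, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "profile_pair_params")
}

# Falling sigmoid: plateau on the left, background on the right, half-max
# at `edge`. softness = 0 degenerates to an exact step (value `plateau`
# strictly before the edge, `background` at and beyond it).
sigmoid_profile <- function(x, edge, softness, plateau, background) {
  if (softness == 0) {
    ifelse(x < edge, plateau, background)
  } else {
    background + (plateau - background) / (1 + exp((x - edge) / softness))
  }
}

#' Generate a paired two-channel linescan with ground truth
#'
#' @param params a [profile_pair_params()] object.
#' @return List with `profile_A`, `profile_B` (both [linescan_profile()]
#'   objects sharing positions) and `ground_truth` (stores the true edge
#'   position and channel offset).
#' @export
generate_profile_pair <- function(params) {
  if (!inherits(params, "profile_pair_params")) {
    params <- do.call(profile_pair_params, as.list(params))
  }
  p <- params
  x <- seq(0, p$profile_length, by = p$sample_spacing)
  ia <- sigmoid_profile(x, p$edge_position, p$edge_softness,
                        p$plateau_A, p$background_A)
  ib <- sigmoid_profile(x, p$edge_position + p$channel_offset,
                        p$edge_softness, p$plateau_B, p$background_B)
  if (p$noise_sd > 0) {
    noise <- with_seed(p$seed, stats::rnorm(2 * length(x), 0, p$noise_sd))
    ia <- pmax(ia + noise[seq_along(x)], 0)
    ib <- pmax(ib + noise[length(x) + seq_along(x)], 0)
  }
  gt <- ground_truth("profile_pair",
                     list(edge_position = p$edge_position,
                          channel_offset = p$channel_offset,
                          sample_spacing = p$sample_spacing,
                          edge_softness = p$edge_softness,
                          noise_sd = p$noise_sd),
                     p$seed)
  list(profile_A = linescan_profile(x, ia, channel = "A",
                                    background = p$background_A,
                                    reference_intensity = p$plateau_A,
                                    sample_spacing = p$sample_spacing),
       profile_B = linescan_profile(x, ib, channel = "B",
                                    background = p$background_B,
                                    reference_intensity = p$plateau_B,
                                    sample_spacing = p$sample_spacing),
       ground_truth = gt)
}
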