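#' Scene specification for the synthetic bead-field generator
#'
#' Describes the geometry of one simulated confocal field: image size, pixel
#' pitch, number of beads and the sieved bead-diameter distribution. Diameters
#' are drawn from a normal distribution truncated to the sieving window
#' (100--120 um), emulating beads passed through a 100 um strainer and a
#' 120 um filter.
#'
#' @param image_height_px,image_width_px Image size in pixels.
#' @param pixel_size_um Pixel pitch in um/pixel.
#' @param n_beads Number of beads to place (>= 0).
#' @param bead_diameter_mean_um,bead_diameter_sd_um Mean and SD of the bead
#'   diameter in um before truncation to `diameter_range_um`.
#' @param diameter_range_um Sieving window; sampled diameters always fall
#'   inside it.
#' @param allow_border If `FALSE`, bead centers stay at least one radius from
#'   every image edge.
#' @param min_center_separation_factor Minimum center distance between two
#'   beads, as a multiple of the sum of their radii. Values < 1 permit
#'   overlapping beads (a stress mode, not the default).
#' @param blank_fraction Fraction of beads rendered blank (no signal in any
#'   channel), emulating beads that carry no immobilized RNA.
#' @return A `cona_scene_spec` list.
#' @export
scene_spec <- function(image_height_px = 1024L, image_width_px = 1024L,
                       pixel_size_um = 1.0, n_beads = 20L,
                       bead_diameter_mean_um = 110, bead_diameter_sd_um = 4,
                       diameter_range_um = c(100, 120),
                       allow_border = FALSE,
                       min_center_separation_factor = 1.05,
                       blank_fraction = 0) {
  stopifnot(image_height_px >= 1, image_width_px >= 1,
            pixel_size_um > 0, n_beads >= 0,
            bead_diameter_sd_um >= 0,
            length(diameter_range_um) == 2,
            diameter_range_um[1] > 0,
            diameter_range_um[1] < diameter_range_um[2],
            blank_fraction >= 0, blank_fraction <= 1)
  structure(list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_size_um = pixel_size_um,
    n_beads = as.integer(n_beads),
    bead_diameter_mean_um = bead_diameter_mean_um,
    bead_diameter_sd_um = bead_diameter_sd_um,
    diameter_range_um = diameter_range_um,
    allow_border = isTRUE(allow_border),
    min_center_separation_factor = min_center_separation_factor,
    blank_fraction = blank_fraction
  ), class = "cona_scene_spec")
}

#' Channel specification for the synthetic generator
#'
#' One fluorescence channel of the simulated read-out. Surface-bound
#' fluorophores appear as a bright ring on the bead periphery: the radial
#' intensity profile is a Gaussian of width `ring_width_sigma_um` centered on
#' the bead radius, on top of a uniform background and an optional faint
#' interior (lumen) fill.
#'
#' @param name Channel label, e.g. `"FITC"` (RNA) or `"mCherry"` (protein).
#' @param ring_amplitude Mean ring amplitude across beads, in arbitrary
#'   intensity units (AU).
#' @param ring_amplitude_cv Bead-to-bead coefficient of variation of the ring
#'   amplitude (dimensionless).
#' @param ring_width_sigma_um Radial Gaussian width of the ring, um.
#' @param interior_level Intensity added inside the bead (AU). Defaults to 0
#'   so the ring-intensity ratio of two channels equals their amplitude ratio.
#' @param background_level Uniform background (AU).
#' @param read_noise_sd SD of additive Gaussian read noise (AU).
#' @param shot_noise If `TRUE`, pixel values are Poisson-distributed around the
#'   noiseless signal.
#' @param blur_sigma_px Gaussian optical blur applied to the noiseless image,
#'   in pixels (0 disables).
#' @return A `cona_channel_spec` list.
#' @export
channel_spec <- function(name, ring_amplitude = 1000,
                         ring_amplitude_cv = 0.05,
                         ring_width_sigma_um = 3,
                         interior_level = 0, background_level = 50,
                         read_noise_sd = 5, shot_noise = TRUE,
                         blur_sigma_px = 0) {
  stopifnot(is.character(name), nchar(name) > 0,
            ring_amplitude >= 0, ring_amplitude_cv >= 0,
            ring_width_sigma_um > 0, interior_level >= 0,
            background_level >= 0, read_noise_sd >= 0, blur_sigma_px >= 0)
  structure(list(
    name = name, ring_amplitude = ring_amplitude,
    ring_amplitude_cv = ring_amplitude_cv,
    ring_width_sigma_um = ring_width_sigma_um,
    interior_level = interior_level, background_level = background_level,
    read_noise_sd = read_noise_sd, shot_noise = isTRUE(shot_noise),
    blur_sigma_px = blur_sigma_px
  ), class = "cona_channel_spec")
}

#' Default two-channel set: an RNA reference channel and a protein channel
#'
#' @param rna_amplitude,protein_amplitude Mean ring amplitudes (AU).
#' @param ... Passed to [channel_spec()] for both channels.
#' @return A named list of two `cona_channel_spec` objects.
#' @export
default_channels <- function(rna_amplitude = 800, protein_amplitude = 400, ...) {
  chs <- list(channel_spec("FITC", ring_amplitude = rna_amplitude, ...),
              channel_spec("mCherry", ring_amplitude = protein_amplitude, ...))
  stats::setNames(chs, vapply(chs, `[[`, "", "name"))
}

#' Simulated screening-plate specification
#'
#' Defines a whole simulated plate: a layout of control and compound wells and
#' a ground-truth binding model. The bound fraction of the tagged protein in a
#' compound well follows a four-parameter logistic (4PL) curve of the
#' compound concentration; the protein-channel ring amplitude in that well is
#' the negative-control amplitude scaled by the bound fraction, while the RNA
#' channel is constant across wells (inhibitors attenuate the protein signal
#' without affecting RNA loading).
#'
#' @param layout Data frame with columns `well`, `role`
#'   (`negative_control` / `positive_control` / `compound`), `compound`,
#'   `concentration_uM` (controls leave the last two empty/NA).
#' @param binding Named list with `top`, `bottom`, `ic50`, `hill`: the true
#'   4PL bound-fraction curve. `top` is the bound fraction with no inhibitor.
#' @param positive_bound_fraction Residual bound fraction in positive-control
#'   wells.
#' @param n_fields_per_well Number of imaged fields per well.
#' @param seed Integer seed for the whole plate.
#' @return A `cona_plate_spec` list.
#' @export
plate_sim_spec <- function(layout,
                           binding = list(top = 1, bottom = 0, ic50 = 2, hill = 1),
                           positive_bound_fraction = 0.29,
                           n_fields_per_well = 1L, seed = 1L) {
  layout <- validate_layout(tibble::as_tibble(layout))
  stopifnot(all(c("top", "bottom", "ic50", "hill") %in% names(binding)),
            binding$ic50 > 0, binding$bottom <= binding$top,
            binding$top <= 1, binding$bottom >= 0,
            positive_bound_fraction >= 0, positive_bound_fraction <= 1,
            n_fields_per_well >= 1)
  structure(list(layout = layout, binding = binding,
                 positive_bound_fraction = positive_bound_fraction,
                 n_fields_per_well = as.integer(n_fields_per_well),
                 seed = as.integer(seed)),
            class = "cona_plate_spec")
}

#' Bead-detection parameters
#'
#' @param radius_range_px Expected bead radius range in pixels; derived from
#'   the 100--120 um sieving window at the image's pixel pitch (the default
#'   assumes 1 um/px, with margin for estimation error).
#' @param smoothing_sigma_px Gaussian smoothing applied before thresholding.
#' @param threshold `"auto"` (Otsu on the normalized image, making detection
#'   invariant to overall intensity scale) or an absolute AU value.
#' @param exclude_border Flag beads whose disc extends beyond the image.
#' @param max_overlap_fraction Two loci are flagged `overlap` when their
#'   center distance is below `(1 - max_overlap_fraction)` times the sum of
#'   their radii.
#' @return A `cona_detect_params` list.
#' @export
detect_params <- function(radius_range_px = c(45, 65),
                          smoothing_sigma_px = 2,
                          threshold = "auto",
                          exclude_border = TRUE,
                          max_overlap_fraction = 0) {
  stopifnot(length(radius_range_px) == 2, radius_range_px[1] > 0,
            radius_range_px[1] < radius_range_px[2],
            smoothing_sigma_px >= 0,
            identical(threshold, "auto") || (is.numeric(threshold) && threshold >= 0),
            max_overlap_fraction >= 0, max_overlap_fraction < 1)
  structure(list(radius_range_px = radius_range_px,
                 smoothing_sigma_px = smoothing_sigma_px,
                 threshold = threshold,
                 exclude_border = isTRUE(exclude_border),
                 max_overlap_fraction = max_overlap_fraction),
            class = "cona_detect_params")
}

#' Ring-quantification parameters
#'
#' @param angles Chord angles in degrees; three uniformly spaced chords by
#'   default, i.e. three measurements across each ring.
#' @param search_window_frac Half-width of the annular peak-search window as a
#'   fraction of the bead radius.
#' @param profile_step_px Sampling step along each chord, pixels.
#' @param min_peaks Minimum number of peripheral peaks (out of `2 * length(angles)`)
#'   required for a valid ring intensity.
#' @param min_reference_intensity Beads whose background-subtracted reference
#'   (RNA) ring intensity falls below this AU value are marked invalid as
#'   blank beads.
#' @param background_margin_px Margin beyond the bead radius excluded from the
#'   field background estimate.
#' @param background_subtract Subtract the field background from peak heights
#'   (set `FALSE` to report raw peak AU).
#' @param statistic `"peaks"` (mean of the profile peak heights, the default)
#'   or `"annulus"` (mean intensity over the annulus `radius +/- window`).
#' @return A `cona_quant_params` list.
#' @export
quant_params <- function(angles = c(0, 60, 120),
                         search_window_frac = 0.2,
                         profile_step_px = 0.5,
                         min_peaks = 4,
                         min_reference_intensity = 50,
                         background_margin_px = 10,
                         background_subtract = TRUE,
                         statistic = c("peaks", "annulus")) {
  statistic <- match.arg(statistic)
  stopifnot(length(angles) >= 1, search_window_frac > 0, search_window_frac < 1,
            profile_step_px > 0, min_peaks >= 1,
            min_reference_intensity >= 0, background_margin_px >= 0)
  structure(list(angles = angles, search_window_frac = search_window_frac,
                 profile_step_px = profile_step_px, min_peaks = min_peaks,
                 min_reference_intensity = min_reference_intensity,
                 background_margin_px = background_margin_px,
                 background_subtract = isTRUE(background_subtract),
                 statistic = statistic),
            class = "cona_quant_params")
}

#' @export
print.cona_scene_spec <- function(x, ...) {
  cat(sprintf("<scene: %d x %d px @ %.2g um/px, %d beads, diameter %g +/- %g um in [%g, %g]>\n",
              x$image_height_px, x$image_width_px, x$pixel_size_um, x$n_beads,
              x$bead_diameter_mean_um, x$bead_diameter_sd_um,
              x$diameter_range_um[1], x$diameter_range_um[2]))
  invisible(x)
}

#' @export
print.cona_channel_spec <- function(x, ...) {
  cat(sprintf("<channel %s: ring %g AU (cv %g), sigma_r %g um, bg %g AU>\n",
              x$name, x$ring_amplitude, x$ring_amplitude_cv,
              x$ring_width_sigma_um, x$background_level))
  invisible(x)
}
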