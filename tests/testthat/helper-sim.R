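# Shared fixtures: everything is generated in code at test time.

quiet_channels <- function(rna = 800, protein = 400, ...) {
  default_channels(rna_amplitude = rna, protein_amplitude = protein,
                   ring_amplitude_cv = 0, read_noise_sd = 0,
                   shot_noise = FALSE, ...)
}

# The standard 20-bead synthetic scene: 1024 x 1024 px at 1 um/px with the
# default noise model (Poisson shot noise + read noise SD 5 AU on ring
# amplitudes of hundreds of AU, i.e. SNR >> 10).
standard_scene <- function(seed = 101) {
  generate_scene(scene_spec(), default_channels(), seed = seed)
}

# Render a single hand-placed bead (noiseless unless stated) and return
# images + its truth row.
single_bead_scene <- function(center = c(150, 150), radius = 55,
                              amplitudes = c(FITC = 800, mCherry = 400),
                              size = 300, background = 50, interior = 0,
                              sigma_um = 3) {
  spec <- scene_spec(image_height_px = size, image_width_px = size, n_beads = 1)
  amp_cols <- stats::setNames(as.list(amplitudes),
                              paste0("amplitude_", names(amplitudes)))
  truth <- tibble::tibble(bead_id = 1L, center_row = center[1],
                          center_col = center[2], radius_px = radius,
                          is_blank = FALSE, !!!amp_cols)
  chs <- lapply(names(amplitudes), function(nm) {
    channel_spec(nm, ring_amplitude = amplitudes[[nm]], ring_amplitude_cv = 0,
                 background_level = background, interior_level = interior,
                 ring_width_sigma_um = sigma_um,
                 read_noise_sd = 0, shot_noise = FALSE)
  })
  names(chs) <- names(amplitudes)
  images <- lapply(chs, function(ch)
    conascreen:::render_channel_noiseless(spec, ch, truth))
  list(images = images, truth = truth)
}

# Match detected loci to truth by nearest center; returns per-truth-row
# index into loci (NA if no locus within max_dist).
match_loci <- function(loci, truth, max_dist = 5) {
  vapply(seq_len(nrow(truth)), function(i) {
    d <- sqrt((loci$center_row - truth$center_row[i])^2 +
                (loci$center_col - truth$center_col[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] <= max_dist) j else NA_integer_
  }, integer(1))
}

# Synthetic per-bead measurement table for wells at a common true ratio.
simulate_null_measurements <- function(wells, true_ratio = 0.93,
                                       bead_cv = 0.05, beads_per_well = 12) {
  purrr::map_dfr(wells, function(w) {
    tibble::tibble(well = w, bead_id = seq_len(beads_per_well),
                   ratio = stats::rnorm(beads_per_well, true_ratio,
                                        bead_cv * true_ratio),
                   valid = TRUE)
  })
}
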