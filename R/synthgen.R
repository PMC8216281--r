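#' Generate one synthetic two-channel bead field with ground truth
#'
#' Simulates a single confocal section through a population of sieved agarose
#' beads. Each bead contributes, per channel, a Gaussian ring of intensity
#' centered on its radius (surface-bound fluorophore seen edge-on), an
#' optional uniform interior fill, on a uniform background. The noiseless
#' pixel model at position p is
#' \deqn{I(p) = b + c \cdot [d(p) \le R] + A \exp(-(d(p) - R)^2 / 2\sigma_r^2)}
#' summed over beads, where d(p) is the distance to the bead center, b the
#' background, c the interior level, A the bead's ring amplitude and
#' \eqn{\sigma_r} the radial ring width. Optional Gaussian optical blur is
#' applied to the noiseless image, then Poisson shot noise and additive
#' Gaussian read noise.
#'
#' Bead diameters are drawn from a truncated normal inside the sieving
#' window; centers are placed by rejection sampling under a minimum
#' center-separation constraint. Identical `spec`, `channels` and `seed`
#' reproduce bit-identical images and truth.
#'
#' @param spec A [scene_spec()].
#' @param channels List of [channel_spec()] objects (one image per channel).
#' @param seed Integer seed.
#' @return List with `images` (named list of numeric matrices, AU) and
#'   `truth`, a tibble with one row per bead: `bead_id`, `center_row`,
#'   `center_col` (0-based, sub-pixel), `radius_px`, `is_blank` and one
#'   `amplitude_<channel>` column per channel.
#' @export
generate_scene <- function(spec, channels, seed) {
  stopifnot(inherits(spec, "cona_scene_spec"))
  channels <- as_channel_list(channels)
  with_seed(seed, {
    truth <- sample_truth(spec, channels)
    images <- lapply(channels, function(ch) render_channel(spec, ch, truth))
    names(images) <- names(channels)
    list(images = images, truth = truth)
  })
}

as_channel_list <- function(channels) {
  if (inherits(channels, "cona_channel_spec")) channels <- list(channels)
  stopifnot(length(channels) >= 1,
            all(vapply(channels, inherits, TRUE, "cona_channel_spec")))
  stats::setNames(channels, vapply(channels, `[[`, "", "name"))
}

# Sample bead geometry + per-channel amplitudes (the ground truth).
sample_truth <- function(spec, channels) {
  n <- spec$n_beads
  amp_cols <- stats::setNames(
    lapply(channels, function(ch) numeric(n)), paste0("amplitude_", names(channels)))
  if (n == 0) {
    return(tibble::tibble(bead_id = integer(), center_row = numeric(),
                          center_col = numeric(), radius_px = numeric(),
                          is_blank = logical(), !!!lapply(amp_cols, function(x) numeric(0))))
  }
  diam_um <- rnorm_trunc(n, spec$bead_diameter_mean_um, spec$bead_diameter_sd_um,
                         spec$diameter_range_um[1], spec$diameter_range_um[2])
  radius_px <- diam_um / 2 / spec$pixel_size_um
  centers <- place_beads(spec, radius_px)
  is_blank <- stats::runif(n) < spec$blank_fraction
  amps <- lapply(channels, function(ch) {
    a <- ch$ring_amplitude * pmax(0, stats::rnorm(n, 1, ch$ring_amplitude_cv))
    a[is_blank] <- 0
    a
  })
  tibble::tibble(bead_id = seq_len(n),
                 center_row = centers[, 1], center_col = centers[, 2],
                 radius_px = radius_px, is_blank = is_blank,
                 !!!stats::setNames(amps, paste0("amplitude_", names(channels))))
}

# Rejection-sample bead centers (0-based pixel coordinates).
place_beads <- function(spec, radius_px, max_tries = 5000L, restarts = 5L) {
  n <- length(radius_px)
  H <- spec$image_height_px; W <- spec$image_width_px
  sep <- spec$min_center_separation_factor
  for (attempt in seq_len(restarts)) {
    centers <- matrix(NA_real_, n, 2)
    ok <- TRUE
    for (i in seq_len(n)) {
      r <- radius_px[i]
      lo_r <- if (spec$allow_border) 0 else r
      hi_r <- if (spec$allow_border) H - 1 else H - 1 - r
      lo_c <- if (spec$allow_border) 0 else r
      hi_c <- if (spec$allow_border) W - 1 else W - 1 - r
      if (hi_r < lo_r || hi_c < lo_c) {
        stop("bead radius ", round(r, 1), " px does not fit in a ",
             H, " x ", W, " image with allow_border = FALSE")
      }
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- c(stats::runif(1, lo_r, hi_r), stats::runif(1, lo_c, hi_c))
        if (i == 1) { placed <- TRUE }
        else {
          prev <- centers[seq_len(i - 1), , drop = FALSE]
          d <- sqrt((prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2)
          placed <- all(d >= sep * (radius_px[seq_len(i - 1)] + r))
        }
        if (placed) { centers[i, ] <- cand; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(centers)
  }
  stop("could not place ", n, " beads under the minimum center-separation ",
       "constraint (factor ", sep, ") in a ", H, " x ", W, " px field")
}

# Render one channel. Noise draws consume RNG in channel order.
render_channel <- function(spec, ch, truth) {
  img <- render_channel_noiseless(spec, ch, truth)
  if (ch$blur_sigma_px > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = ch$blur_sigma_px))
  }
  if (ch$shot_noise) {
    img <- matrix(stats::rpois(length(img), pmax(img, 0)),
                  nrow(img), ncol(img))
  }
  if (ch$read_noise_sd > 0) {
    img <- img + stats::rnorm(length(img), 0, ch$read_noise_sd)
  }
  pmax(img, 0)
}

render_channel_noiseless <- function(spec, ch, truth) {
  H <- spec$image_height_px; W <- spec$image_width_px
  img <- matrix(ch$background_level, H, W)
  sigma_r <- ch$ring_width_sigma_um / spec$pixel_size_um
  amp_col <- paste0("amplitude_", ch$name)
  for (i in seq_len(nrow(truth))) {
    A <- truth[[amp_col]][i]
    R <- truth$radius_px[i]
    if (A == 0 && ch$interior_level == 0) next
    r0 <- truth$center_row[i]; c0 <- truth$center_col[i]
    ext <- R + 4 * sigma_r + 1
    rows <- max(1, floor(r0 + 1 - ext)):min(H, ceiling(r0 + 1 + ext))
    cols <- max(1, floor(c0 + 1 - ext)):min(W, ceiling(c0 + 1 + ext))
    d <- sqrt(outer((rows - 1 - r0)^2, (cols - 1 - c0)^2, `+`))
    add <- A * exp(-(d - R)^2 / (2 * sigma_r^2))
    if (ch$interior_level > 0) add <- add + ch$interior_level * (d <= R)
    img[rows, cols] <- img[rows, cols] + add
  }
  img
}

#' Bound fraction of the tagged protein as a function of inhibitor dose
#'
#' Evaluates the ground-truth 4PL binding curve of a simulated plate:
#' `bottom + (top - bottom) / (1 + (conc/ic50)^hill)`; at dose 0 the bound
#' fraction equals `top`.
#'
#' @param concentration_uM Dose(s) in uM.
#' @param binding Named list with `top`, `bottom`, `ic50`, `hill`.
#' @return Numeric bound fraction(s) in `[0, 1]`.
#' @export
bound_fraction <- function(concentration_uM, binding) {
  four_pl(concentration_uM, binding$top, binding$bottom, binding$ic50, binding$hill)
}

#' Simulate a whole screening plate with ground truth
#'
#' Renders every (well, field) of a simulated plate. The protein-channel ring
#' amplitude of each well is the base amplitude scaled by the well's true
#' bound fraction -- `top` of the binding curve for negative controls, the
#' stated residual fraction for positive controls, and the 4PL binding curve
#' evaluated at the well's concentration for compound wells. The RNA channel
#' is identical across wells.
#'
#' @param plate A [plate_sim_spec()].
#' @param scene A [scene_spec()] used for every field.
#' @param channels Named list of [channel_spec()]; `signal_channel` must name
#'   one of them (the protein channel), all others are dose-independent.
#' @param signal_channel Name of the protein (signal) channel.
#' @return List with `fields` (tibble: `well`, `field`, `bound_fraction`,
#'   list-column `images`), `truth` (per-bead truth across all fields, with
#'   `well`/`field`), and `layout`.
#' @export
generate_screen_plate <- function(plate, scene, channels,
                                  signal_channel = "mCherry") {
  stopifnot(inherits(plate, "cona_plate_spec"), inherits(scene, "cona_scene_spec"))
  channels <- as_channel_list(channels)
  if (!signal_channel %in% names(channels)) {
    stop("signal_channel '", signal_channel, "' is not among the channel specs")
  }
  layout <- plate$layout
  bf <- well_bound_fraction(layout, plate)
  n_fields <- plate$n_fields_per_well
  grid <- tidyr::expand_grid(well = layout$well, field = seq_len(n_fields))
  field_seeds <- with_seed(plate$seed,
                           sample.int(.Machine$integer.max - 1L, nrow(grid)))
  res <- purrr::pmap(list(grid$well, grid$field, field_seeds), function(w, f, s) {
    chs <- channels
    frac <- bf[[w]]
    chs[[signal_channel]]$ring_amplitude <-
      channels[[signal_channel]]$ring_amplitude * frac
    sc <- generate_scene(scene, chs, seed = s)
    truth <- dplyr::mutate(sc$truth, well = w, field = f, .before = 1)
    list(images = sc$images, truth = truth, bound_fraction = frac)
  })
  fields <- dplyr::mutate(grid,
                          bound_fraction = purrr::map_dbl(res, "bound_fraction"),
                          images = purrr::map(res, "images"))
  list(fields = fields,
       truth = dplyr::bind_rows(purrr::map(res, "truth")),
       layout = layout)
}

well_bound_fraction <- function(layout, plate) {
  b <- plate$binding
  bf <- vapply(seq_len(nrow(layout)), function(i) {
    switch(layout$role[i],
           negative_control = b$top,
           positive_control = plate$positive_bound_fraction,
           compound = bound_fraction(layout$concentration_uM[i], b),
           stop("unknown role '", layout$role[i], "'"))
  }, numeric(1))
  stats::setNames(bf, layout$well)
}

#' Write a simulated plate to disk in the pipeline's file layout
#'
#' Writes one 16-bit grayscale TIFF per (well, field, channel) named
#' `{well}_{field}_{channel}.tif`, the plate layout CSV and the per-bead
#' ground-truth CSV.
#'
#' @param plate_sim Result of [generate_screen_plate()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_screen_plate <- function(plate_sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(plate_sim$fields))) {
    w <- plate_sim$fields$well[i]; f <- plate_sim$fields$field[i]
    imgs <- plate_sim$fields$images[[i]]
    for (ch in names(imgs)) {
      write_bead_image(imgs[[ch]], file.path(dir, sprintf("%s_%d_%s.tif", w, f, ch)))
    }
  }
  write_layout(plate_sim$layout, file.path(dir, "layout.csv"))
  readr::write_csv(plate_sim$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
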