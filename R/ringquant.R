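#' Estimate the field background of one channel
#'
#' Robust location (median) of the pixels lying farther than
#' `radius + margin_px` from every detected bead center. When beads tile the
#' field so densely that fewer than 1% of pixels remain, falls back to a low
#' percentile of the whole image and warns.
#'
#' @param image Numeric matrix (AU).
#' @param loci Tibble of bead loci (may be empty).
#' @param margin_px Margin beyond each bead radius to exclude, pixels.
#' @return Scalar background estimate (AU).
#' @export
estimate_background <- function(image, loci, margin_px = 10) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (is.null(loci) || nrow(loci) == 0) return(stats::median(image))
  free <- matrix(TRUE, nrow(image), ncol(image))
  for (i in seq_len(nrow(loci))) {
    r0 <- loci$center_row[i]; c0 <- loci$center_col[i]
    ext <- loci$radius_px[i] + margin_px
    rows <- max(1, floor(r0 + 1 - ext)):min(nrow(image), ceiling(r0 + 1 + ext))
    cols <- max(1, floor(c0 + 1 - ext)):min(ncol(image), ceiling(c0 + 1 + ext))
    d2 <- outer((rows - 1 - r0)^2, (cols - 1 - c0)^2, `+`)
    free[rows, cols] <- free[rows, cols] & (d2 > ext^2)
  }
  if (sum(free) < 0.01 * length(image)) {
    warning("fewer than 1% of pixels lie outside all bead margins; ",
            "falling back to the 5th percentile of the whole image")
    return(unname(stats::quantile(image, 0.05)))
  }
  stats::median(image[free])
}

#' Extract chord intensity profiles across one bead
#'
#' Samples the image by bilinear interpolation along chords through the bead
#' center (three chords at 0, 60 and 120 degrees by default -- three
#' measurements across each ring). Each chord runs from `-(R + w)` to
#' `+(R + w)` around the center, where `w = search_window_frac * R` is the
#' annular peak-search half-width. On each side of the center the peripheral
#' peak is the profile maximum within `[R - w, R + w]`, refined to sub-pixel
#' position and height by a local parabolic fit. Chord portions outside the
#' image are truncated; a side whose search window is entirely unavailable
#' yields a missing peak.
#'
#' @param image Numeric matrix (AU).
#' @param locus One-row tibble (or list) with `center_row`, `center_col`,
#'   `radius_px` (0-based pixel coordinates).
#' @param params A [quant_params()].
#' @return A `cona_profiles` list: `bead_id`, `radius_px`, `profiles` (tibble
#'   `angle`, `t`, `intensity`) and `peaks` (tibble `angle`, `side`,
#'   `t_peak`, `height`; `height` is `NA` when missing).
#' @export
extract_profiles <- function(image, locus, params = quant_params()) {
  r0 <- locus$center_row[1]; c0 <- locus$center_col[1]
  R <- locus$radius_px[1]
  stopifnot(R > 0, r0 >= 0, c0 >= 0, r0 <= nrow(image) - 1, c0 <= ncol(image) - 1)
  w <- params$search_window_frac * R
  tt <- seq(-(R + w), R + w, by = params$profile_step_px)
  prof_list <- lapply(params$angles, function(a) {
    th <- a * pi / 180
    rr <- r0 + tt * sin(th)
    cc <- c0 + tt * cos(th)
    # interp2 works on the grid x = columns, y = rows (0-based here)
    val <- pracma::interp2(x = 0:(ncol(image) - 1), y = 0:(nrow(image) - 1),
                           Z = image, xp = cc, yp = rr)
    tibble::tibble(angle = a, t = tt, intensity = val)
  })
  profiles <- dplyr::bind_rows(prof_list)
  peaks <- dplyr::bind_rows(lapply(prof_list, function(p) {
    dplyr::bind_rows(lapply(c(-1, 1), function(s) {
      pk <- profile_peak(p$t, p$intensity, side = s, R = R, w = w)
      tibble::tibble(angle = p$angle[1], side = s,
                     t_peak = pk[["t"]], height = pk[["height"]])
    }))
  }))
  structure(list(bead_id = locus$bead_id[1] %||% NA_integer_,
                 radius_px = R, profiles = profiles, peaks = peaks),
            class = "cona_profiles")
}

# Peak within the annular window on one side of the chord; parabolic
# sub-sample refinement of position and height.
profile_peak <- function(t, y, side, R, w) {
  sel <- which(sign(t) == side & abs(t) >= R - w & abs(t) <= R + w & is.finite(y))
  if (length(sel) == 0) return(c(t = NA_real_, height = NA_real_))
  i <- sel[which.max(y[sel])]
  if (i > 1 && i < length(t) && is.finite(y[i - 1]) && is.finite(y[i + 1])) {
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      delta <- max(-0.5, min(0.5, 0.5 * (y1 - y3) / denom))
      step <- t[2] - t[1]
      return(c(t = t[i] + delta * step,
               height = y2 - 0.25 * (y1 - y3) * delta))
    }
  }
  c(t = t[i], height = y[i])
}

#' Ring intensity of one bead in one channel
#'
#' The mean of the available peripheral peak heights minus the field
#' background, clamped at zero. Requires at least `min_peaks` of the
#' `2 * n_angles` possible peaks; otherwise the measurement is invalid.
#'
#' @param profiles A `cona_profiles` from [extract_profiles()].
#' @param background Field background (AU); ignored when
#'   `background_subtract = FALSE`.
#' @param params A [quant_params()].
#' @return List with `intensity` (AU or `NA`), `n_peaks`, `reason`
#'   (`NA` or `"peaks_missing"`).
#' @export
ring_intensity <- function(profiles, background, params = quant_params()) {
  h <- profiles$peaks$height
  n_ok <- sum(is.finite(h))
  if (n_ok < params$min_peaks) {
    return(list(intensity = NA_real_, n_peaks = n_ok, reason = "peaks_missing"))
  }
  raw <- mean(h[is.finite(h)])
  val <- if (params$background_subtract) max(0, raw - background) else raw
  list(intensity = val, n_peaks = n_ok, reason = NA_character_)
}

# Integrated-annulus alternative: mean background-subtracted intensity over
# the annulus radius +/- w.
annulus_intensity <- function(image, locus, background, params) {
  r0 <- locus$center_row[1]; c0 <- locus$center_col[1]
  R <- locus$radius_px[1]
  w <- params$search_window_frac * R
  ext <- R + w
  rows <- max(1, floor(r0 + 1 - ext)):min(nrow(image), ceiling(r0 + 1 + ext))
  cols <- max(1, floor(c0 + 1 - ext)):min(ncol(image), ceiling(c0 + 1 + ext))
  d <- sqrt(outer((rows - 1 - r0)^2, (cols - 1 - c0)^2, `+`))
  px <- image[rows, cols][d >= R - w & d <= R + w]
  val <- mean(px)
  if (params$background_subtract) val <- max(0, val - background)
  list(intensity = val, n_peaks = NA_integer_, reason = NA_character_)
}

#' Measure one bead across all channels and form the protein/RNA ratio
#'
#' Quantifies the ring intensity of an unflagged bead locus in every channel
#' and reports `ratio` = signal (protein) ring intensity / reference (RNA)
#' ring intensity. Beads whose reference ring intensity falls below
#' `min_reference_intensity` are invalid with reason `blank_bead` (a bead
#' carrying no RNA cannot report binding); division by zero never occurs.
#'
#' @param images Named list of channel images (AU).
#' @param locus One-row tibble with `bead_id`, `center_row`, `center_col`,
#'   `radius_px`.
#' @param backgrounds Named numeric vector/list of per-channel backgrounds (AU).
#' @param reference_channel,signal_channel Channel names.
#' @param params A [quant_params()].
#' @return One-row tibble: `bead_id`, one `ring_<channel>` column per
#'   channel, `ratio`, `valid`, `invalid_reason`.
#' @export
measure_bead <- function(images, locus, backgrounds,
                         reference_channel = "FITC", signal_channel = "mCherry",
                         params = quant_params()) {
  stopifnot(all(c(reference_channel, signal_channel) %in% names(images)))
  vals <- lapply(names(images), function(ch) {
    if (params$statistic == "annulus") {
      annulus_intensity(images[[ch]], locus, backgrounds[[ch]], params)
    } else {
      pr <- extract_profiles(images[[ch]], locus, params)
      ring_intensity(pr, backgrounds[[ch]], params)
    }
  })
  names(vals) <- names(images)
  ring <- vapply(vals, `[[`, numeric(1), "intensity")
  reason <- NA_character_
  valid <- TRUE
  bad <- vapply(vals, function(v) !is.na(v$reason), logical(1))
  if (any(bad)) {
    valid <- FALSE
    reason <- vals[[which(bad)[1]]]$reason
  } else if (ring[[reference_channel]] < params$min_reference_intensity) {
    valid <- FALSE
    reason <- "blank_bead"
  }
  ratio <- if (valid) ring[[signal_channel]] / ring[[reference_channel]] else NA_real_
  tibble::tibble(bead_id = locus$bead_id[1] %||% NA_integer_,
                 !!!stats::setNames(as.list(ring), paste0("ring_", names(ring))),
                 ratio = ratio, valid = valid, invalid_reason = reason)
}

#' Measure every clean bead in one field
#'
#' Estimates each channel's field background, then measures every locus that
#' carries no QC flag. Flagged loci are excluded here (not at detection),
#' keeping the QC audit trail intact.
#'
#' @param images Named list of channel images for one (well, field).
#' @param loci Tibble from [detect_beads()].
#' @param reference_channel,signal_channel Channel names.
#' @param params A [quant_params()].
#' @return Tibble of per-bead measurements (see [measure_bead()]); zero rows
#'   when no clean locus exists.
#' @export
measure_field <- function(images, loci,
                          reference_channel = "FITC", signal_channel = "mCherry",
                          params = quant_params()) {
  clean <- loci[is_clean_locus(loci), , drop = FALSE]
  bgs <- lapply(images, estimate_background, loci = loci,
                margin_px = params$background_margin_px)
  if (nrow(clean) == 0) {
    return(tibble::tibble(bead_id = integer(),
                          !!!stats::setNames(rep(list(numeric(0)), length(images)),
                                             paste0("ring_", names(images))),
                          ratio = numeric(), valid = logical(),
                          invalid_reason = character()))
  }
  purrr::map_dfr(seq_len(nrow(clean)), function(i) {
    measure_bead(images, clean[i, ], bgs,
                 reference_channel = reference_channel,
                 signal_channel = signal_channel, params = params)
  })
}
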