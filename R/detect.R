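#' Detect beads in a reference-channel image
#'
#' Locates beads as bright rings in a single-channel image and returns one
#' quality-flagged locus per bead. Detection runs on the RNA (reference)
#' channel by convention, since every non-blank bead carries immobilized RNA;
#' blank beads show no ring there and are never measured.
#'
#' Algorithm: Gaussian smoothing, global threshold (Otsu on the min-max
#' normalized image by default, which makes the result invariant to overall
#' intensity scale), hole filling so each ring becomes a disc, connected-
#' component labeling, then per component a centroid and a radius estimated
#' from the peak of the radial intensity profile around the centroid
#' (parabolically refined to sub-pixel precision).
#'
#' Loci carry `qc_flags` (semicolon-joined): `border` (bead disc extends
#' beyond the image), `overlap` (two loci closer than the sum of their radii,
#' or a markedly non-circular fused component), `size_out_of_range` (radius
#' outside `radius_range_px`). Flagged loci are excluded from measurement by
#' default, never silently dropped.
#'
#' @param image Numeric matrix (AU), finite and non-negative.
#' @param params A [detect_params()].
#' @return Tibble with `bead_id`, `center_row`, `center_col` (0-based,
#'   sub-pixel), `radius_px`, `qc_flags` (empty string when clean), sorted by
#'   (`center_row`, `center_col`).
#' @export
detect_beads <- function(image, params = detect_params()) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  rng <- params$radius_range_px
  if (nrow(image) < 2 * rng[2] || ncol(image) < 2 * rng[2]) {
    stop("image (", nrow(image), " x ", ncol(image),
         ") is smaller than twice the maximum bead radius (", rng[2], " px)")
  }
  empty <- tibble::tibble(bead_id = integer(), center_row = numeric(),
                          center_col = numeric(), radius_px = numeric(),
                          qc_flags = character())
  span <- diff(range(image))
  if (span == 0) return(empty)

  sm <- if (params$smoothing_sigma_px > 0)
    as.matrix(EBImage::gblur(image, sigma = params$smoothing_sigma_px)) else image
  norm <- (sm - min(sm)) / (max(sm) - min(sm))
  thr <- if (identical(params$threshold, "auto")) {
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    (params$threshold - min(sm)) / (max(sm) - min(sm))
  }
  ring <- norm > thr           # thin annulus band per bead
  mask <- EBImage::fillHull(EBImage::Image(ring))
  # watershed on the distance map separates touching (but distinct) beads;
  # the tolerance merges shallow spurious maxima inside a single bead
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = 0.3 * rng[1], ext = 1)
  labm <- as.matrix(EBImage::imageData(lab))
  nlab <- max(labm)
  if (nlab == 0) return(empty)

  min_area <- pi * (0.5 * rng[1])^2
  loci <- purrr::map_dfr(seq_len(nlab), function(k) {
    idx <- which(labm == k, arr.ind = TRUE)
    touches <- any(idx[, 1] == 1 | idx[, 1] == nrow(image) |
                     idx[, 2] == 1 | idx[, 2] == ncol(image))
    if (touches) {
      # a component clipped by the image edge: centroid and radial profile
      # are biased, so recover the circle geometrically from its ring-band
      # pixels (a partial annulus) and judge the flags from that geometry
      on_ring <- ring[idx]
      if (sum(on_ring) < 30) return(NULL)
      fit <- kasa_circle_fit(idx[on_ring, 1] - 1, idx[on_ring, 2] - 1)
      if (is.null(fit)) return(NULL)
      flags <- character()
      if (fit$radius < rng[1] || fit$radius > rng[2]) {
        flags <- c(flags, "size_out_of_range")
      }
      if (params$exclude_border &&
          (fit$row - fit$radius < 0 || fit$row + fit$radius > nrow(image) - 1 ||
           fit$col - fit$radius < 0 || fit$col + fit$radius > ncol(image) - 1)) {
        flags <- c(flags, "border")
      }
      return(tibble::tibble(center_row = fit$row, center_col = fit$col,
                            radius_px = fit$radius,
                            qc_flags = paste(flags, collapse = ";")))
    }
    if (nrow(idx) < min_area) return(NULL)
    r0 <- mean(idx[, 1]) - 1  # 0-based
    c0 <- mean(idx[, 2]) - 1
    rad <- radial_peak_radius(sm, r0, c0, rng)
    if (is.na(rad)) return(NULL)
    flags <- character()
    if (rad < rng[1] || rad > rng[2]) flags <- c(flags, "size_out_of_range")
    # fused bead masses are non-circular: compare component area to pi r^2
    area_ratio <- nrow(idx) / (pi * rad^2)
    if (area_ratio > 1.6) flags <- c(flags, "overlap")
    if (params$exclude_border &&
        (r0 - rad < 0 || r0 + rad > nrow(image) - 1 ||
         c0 - rad < 0 || c0 + rad > ncol(image) - 1)) {
      flags <- c(flags, "border")
    }
    tibble::tibble(center_row = r0, center_col = c0, radius_px = rad,
                   qc_flags = paste(flags, collapse = ";"))
  })
  if (nrow(loci) == 0) return(empty)

  # pairwise overlap between distinct loci
  if (nrow(loci) > 1) {
    d <- as.matrix(stats::dist(cbind(loci$center_row, loci$center_col)))
    rsum <- outer(loci$radius_px, loci$radius_px, `+`) *
      (1 - params$max_overlap_fraction)
    diag(d) <- Inf
    hit <- apply(d < rsum, 1, any)
    loci$qc_flags <- vapply(seq_len(nrow(loci)), function(i) {
      fl <- strsplit(loci$qc_flags[i], ";", fixed = TRUE)[[1]]
      fl <- fl[nzchar(fl)]
      if (hit[i]) fl <- union(fl, "overlap")
      paste(fl, collapse = ";")
    }, character(1))
  }
  loci <- dplyr::arrange(loci, .data$center_row, .data$center_col)
  dplyr::mutate(loci, bead_id = dplyr::row_number(), .before = 1)
}

# Algebraic (Kasa) least-squares circle fit through a set of 0-based pixel
# coordinates; returns NULL for degenerate (collinear) input.
kasa_circle_fit <- function(rows0, cols0) {
  A <- cbind(2 * rows0, 2 * cols0, 1)
  b <- rows0^2 + cols0^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(row = sol[1], col = sol[2], radius = sqrt(r2))
}

# Radius from the argmax of the mean radial intensity profile around
# (r0, c0), with parabolic sub-pixel refinement. Returns NA when no interior
# maximum exists in the search band.
radial_peak_radius <- function(image, r0, c0, radius_range, pad = 1.3) {
  rmax <- pad * radius_range[2]
  rows <- max(1, floor(r0 + 1 - rmax)):min(nrow(image), ceiling(r0 + 1 + rmax))
  cols <- max(1, floor(c0 + 1 - rmax)):min(ncol(image), ceiling(c0 + 1 + rmax))
  d <- sqrt(outer((rows - 1 - r0)^2, (cols - 1 - c0)^2, `+`))
  bin <- round(d)
  keep <- bin <= ceiling(rmax)
  prof <- tapply(image[rows, cols][keep], bin[keep], mean)
  r_bins <- as.numeric(names(prof))
  band <- r_bins >= 0.6 * radius_range[1] & r_bins <= rmax
  if (!any(band)) return(NA_real_)
  prof <- prof[band]; r_bins <- r_bins[band]
  i <- which.max(prof)
  if (i == 1 || i == length(prof)) return(r_bins[i])
  y1 <- prof[i - 1]; y2 <- prof[i]; y3 <- prof[i + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom < 0) 0.5 * (y1 - y3) / denom else 0
  r_bins[i] + max(-0.5, min(0.5, delta)) * (r_bins[2] - r_bins[1])
}

#' Split semicolon-joined QC flags into a logical "is clean" vector
#'
#' @param loci Tibble from [detect_beads()].
#' @return Logical vector, `TRUE` where the locus carries no QC flag.
#' @export
is_clean_locus <- function(loci) {
  f <- loci$qc_flags
  if (is.null(f)) f <- rep("", nrow(loci))
  f[is.na(f)] <- ""
  !nzchar(f)
}
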