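test_that("background estimation: constant field, noisy scene, degenerate coverage", {
  empty <- tibble::tibble(center_row = numeric(), center_col = numeric(),
                          radius_px = numeric())
  expect_equal(estimate_background(matrix(37.5, 100, 100), empty), 37.5)

  sc <- generate_scene(scene_spec(image_height_px = 512, image_width_px = 512,
                                  n_beads = 5), default_channels(), seed = 21)
  loci <- detect_beads(sc$images$FITC)
  bg <- estimate_background(sc$images$FITC, loci)
  expect_lt(abs(bg - 50) / 50, 0.05)

  giant <- tibble::tibble(center_row = 100, center_col = 100, radius_px = 400)
  expect_warning(fb <- estimate_background(matrix(c(1, rep(10, 39999)), 200, 200),
                                           giant, margin_px = 10),
                 "1%")
  expect_lt(fb, 11)
})

test_that("profiles of a null image are identically zero", {
  img <- matrix(0, 120, 120)
  locus <- tibble::tibble(bead_id = 1L, center_row = 60, center_col = 60,
                          radius_px = 30)
  pr <- extract_profiles(img, locus)
  expect_equal(nrow(dplyr::distinct(pr$profiles, angle)), 3)
  expect_true(all(pr$profiles$intensity == 0, na.rm = TRUE))
  expect_true(all(pr$peaks$height == 0))
})

test_that("a noiseless rendered ring yields six peaks at background + amplitude", {
  sb <- single_bead_scene(amplitudes = c(FITC = 1000), background = 50)
  pr <- extract_profiles(sb$images$FITC, sb$truth)
  expect_equal(nrow(pr$peaks), 6)          # 3 chords x 2 sides
  expect_true(all(is.finite(pr$peaks$height)))
  expect_true(all(abs(pr$peaks$height - 1050) / 1050 < 0.02))
  # peak positions sit at the radius
  expect_true(all(abs(abs(pr$peaks$t_peak) - 55) < 1.5))
})

test_that("a chord exiting the image truncates and marks that side's peak missing", {
  sb <- single_bead_scene(center = c(150, 40), radius = 55,
                          amplitudes = c(FITC = 1000), size = 300)
  pr <- extract_profiles(sb$images$FITC, tibble::tibble(
    bead_id = 1L, center_row = 150, center_col = 40, radius_px = 55))
  # the left (side = -1) horizontal search window lies outside the image
  left0 <- pr$peaks[pr$peaks$angle == 0 & pr$peaks$side == -1, ]
  expect_true(is.na(left0$height))
  # interior sides remain measurable
  expect_gte(sum(is.finite(pr$peaks$height)), 4)
})

test_that("ring intensity is the clamped background-subtracted mean of peaks", {
  fake <- function(h) structure(list(bead_id = 1L, radius_px = 55,
                                     peaks = tibble::tibble(height = h)),
                                class = "cona_profiles")
  expect_equal(ring_intensity(fake(rep(1050, 6)), 50)$intensity, 1000)
  expect_equal(ring_intensity(fake(rep(50, 6)), 50)$intensity, 0)
  res <- ring_intensity(fake(c(1050, 1050, 1050, NA, NA, NA)), 50)
  expect_true(is.na(res$intensity))
  expect_equal(res$reason, "peaks_missing")
})

test_that("noiseless two-channel bead recovers the amplitude ratio", {
  sb <- single_bead_scene(amplitudes = c(FITC = 800, mCherry = 400))
  bgs <- list(FITC = 50, mCherry = 50)
  m <- measure_bead(sb$images, sb$truth, bgs)
  expect_true(m$valid)
  expect_lt(abs(m$ratio - 0.5) / 0.5, 0.02)
})

test_that("zero protein gives ratio 0; a blank bead is invalid, never a division", {
  sb <- single_bead_scene(amplitudes = c(FITC = 800, mCherry = 0))
  m <- measure_bead(sb$images, sb$truth, list(FITC = 50, mCherry = 50))
  expect_true(m$valid)
  expect_equal(m$ratio, 0)

  blank <- single_bead_scene(amplitudes = c(FITC = 0, mCherry = 0))
  m2 <- measure_bead(blank$images, blank$truth, list(FITC = 50, mCherry = 50))
  expect_false(m2$valid)
  expect_equal(m2$invalid_reason, "blank_bead")
  expect_true(is.na(m2$ratio))
})

test_that("median estimated ratio over many noisy beads is within 10% of truth", {
  ratios <- purrr::map(1:9, function(s) {
    sc <- generate_scene(scene_spec(image_height_px = 900, image_width_px = 900,
                                    n_beads = 12), default_channels(), seed = 300 + s)
    loci <- detect_beads(sc$images$FITC)
    measure_field(sc$images, loci)$ratio
  })
  ratios <- unlist(ratios)
  expect_gte(length(ratios), 100)
  expect_lt(abs(median(ratios, na.rm = TRUE) - 0.5) / 0.5, 0.10)
})

test_that("estimated ratio is monotone in the true protein amplitude (noiseless)", {
  amps <- c(100, 200, 400, 600, 800)
  est <- vapply(amps, function(a) {
    sb <- single_bead_scene(amplitudes = c(FITC = 800, mCherry = a))
    measure_bead(sb$images, sb$truth, list(FITC = 50, mCherry = 50))$ratio
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  # proportionality of the ratio read-out to the bound-protein level
  fit <- lm(est ~ amps)
  expect_gte(summary(fit)$r.squared, 0.98)
})

test_that("the integrated-annulus statistic agrees with the peak statistic in rank", {
  sb <- single_bead_scene(amplitudes = c(FITC = 800, mCherry = 400))
  p_ann <- quant_params(statistic = "annulus")
  m <- measure_bead(sb$images, sb$truth, list(FITC = 50, mCherry = 50),
                    params = p_ann)
  expect_true(m$valid)
  # annulus averages over the Gaussian shoulder, so values are lower than the
  # peak statistic, but the two-channel ratio is preserved
  expect_lt(abs(m$ratio - 0.5) / 0.5, 0.05)
})
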