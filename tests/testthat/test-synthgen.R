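test_that("an empty scene is pure background with empty truth", {
  spec <- scene_spec(image_height_px = 128, image_width_px = 128, n_beads = 0)
  sc <- generate_scene(spec, quiet_channels(), seed = 1)
  expect_equal(nrow(sc$truth), 0)
  for (img in sc$images) {
    expect_true(all(img == 50))
  }
})

test_that("identical spec and seed reproduce bit-identical images and truth", {
  spec <- scene_spec(image_height_px = 256, image_width_px = 256, n_beads = 3)
  a <- generate_scene(spec, default_channels(), seed = 42)
  b <- generate_scene(spec, default_channels(), seed = 42)
  expect_identical(a$images, b$images)
  expect_identical(a$truth, b$truth)
  c <- generate_scene(spec, default_channels(), seed = 43)
  expect_false(identical(a$images, c$images))
})

test_that("truth of the standard 20-bead scene respects the geometry constraints", {
  sc <- standard_scene()
  tr <- sc$truth
  expect_equal(nrow(tr), 20)
  # sieving window 100-120 um at 1 um/px -> radii in [50, 60] px
  expect_true(all(tr$radius_px >= 50 & tr$radius_px <= 60))
  # allow_border = FALSE: centers at least one radius from every edge
  expect_true(all(tr$center_row >= tr$radius_px))
  expect_true(all(tr$center_col >= tr$radius_px))
  expect_true(all(tr$center_row <= 1023 - tr$radius_px))
  expect_true(all(tr$center_col <= 1023 - tr$radius_px))
  # minimum center separation factor 1.05
  d <- as.matrix(dist(cbind(tr$center_row, tr$center_col)))
  rsum <- outer(tr$radius_px, tr$radius_px, `+`)
  diag(d) <- Inf
  expect_true(all(d >= 1.05 * rsum - 1e-9))
})

test_that("noiseless rings peak at the bead radius with the stated amplitude", {
  spec <- scene_spec(image_height_px = 400, image_width_px = 400, n_beads = 3)
  sc <- generate_scene(spec, quiet_channels(), seed = 7)
  img <- sc$images$FITC
  for (i in seq_len(nrow(sc$truth))) {
    r0 <- sc$truth$center_row[i]; c0 <- sc$truth$center_col[i]
    R <- sc$truth$radius_px[i]; A <- sc$truth$amplitude_FITC[i]
    row <- round(r0) + 1
    vals <- img[row, ]
    cols0 <- seq_len(ncol(img)) - 1
    side <- vals
    side[abs(cols0 - c0) < R / 2] <- -Inf       # look at the periphery only
    side[abs(cols0 - c0) > R * 1.4] <- -Inf
    peak_col <- cols0[which.max(side)]
    expect_lt(abs(abs(peak_col - c0) - R), 1 + abs(round(r0) - r0) + 0.5)
    expect_lt(abs(max(side) - (50 + A)) / (50 + A), 0.02)
  }
})

test_that("increasing ring amplitude strictly increases the noiseless maximum", {
  maxima <- vapply(c(200, 400, 800, 1600), function(a) {
    ch <- channel_spec("FITC", ring_amplitude = a, ring_amplitude_cv = 0,
                       read_noise_sd = 0, shot_noise = FALSE)
    sc <- generate_scene(scene_spec(image_height_px = 256, image_width_px = 256,
                                    n_beads = 2), list(ch), seed = 5)
    max(sc$images$FITC)
  }, numeric(1))
  expect_true(all(diff(maxima) > 0))
})

test_that("blank beads carry zero amplitude in every channel", {
  spec <- scene_spec(image_height_px = 256, image_width_px = 256, n_beads = 4,
                     blank_fraction = 1)
  sc <- generate_scene(spec, default_channels(), seed = 3)
  expect_true(all(sc$truth$is_blank))
  expect_true(all(sc$truth$amplitude_FITC == 0))
  expect_true(all(sc$truth$amplitude_mCherry == 0))
})

test_that("placement fails with a clear error when beads cannot fit", {
  spec <- scene_spec(image_height_px = 130, image_width_px = 130, n_beads = 3)
  expect_error(generate_scene(spec, quiet_channels(), seed = 1),
               "separation|fit")
})

test_that("plate truth scales the protein amplitude by the 4PL bound fraction", {
  lay <- control_plate_layout(2, 2)
  lay <- rbind(lay, tibble::tibble(well = "C02", role = "compound",
                                   compound = "cmpA", concentration_uM = 2))
  plate <- plate_sim_spec(lay, binding = list(top = 1, bottom = 0,
                                              ic50 = 2, hill = 1),
                          positive_bound_fraction = 0.29, seed = 11)
  sc <- scene_spec(image_height_px = 256, image_width_px = 256, n_beads = 2)
  chs <- quiet_channels()
  sim <- generate_screen_plate(plate, sc, chs)
  tr <- sim$truth
  # dose = true IC50 of a (1, 0) curve -> half the negative-control amplitude
  expect_equal(unique(tr$amplitude_mCherry[tr$well == "C02"]), 400 * 0.5)
  expect_equal(unique(tr$amplitude_mCherry[tr$well %in% c("B02", "B03")]), 400)
  expect_equal(unique(tr$amplitude_mCherry[tr$well %in% c("B04", "B05")]),
               400 * 0.29)
  # RNA channel untouched by dose
  expect_equal(unique(tr$amplitude_FITC), 800)
})

test_that("a null plate (all compound doses zero) matches the negative controls", {
  lay <- rbind(control_plate_layout(2, 0),
               tibble::tibble(well = c("C02", "C03"), role = "compound",
                              compound = c("a", "b"), concentration_uM = 0))
  plate <- plate_sim_spec(lay, seed = 2)
  sim <- generate_screen_plate(plate,
                               scene_spec(image_height_px = 256,
                                          image_width_px = 256, n_beads = 1),
                               quiet_channels())
  expect_equal(unique(sim$fields$bound_fraction), 1)
  expect_true(all(sim$truth$amplitude_mCherry == 400))
})

test_that("unknown layout roles are rejected", {
  lay <- tibble::tibble(well = "B02", role = "mystery", compound = NA,
                        concentration_uM = NA)
  expect_error(plate_sim_spec(lay), "unknown role")
})
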