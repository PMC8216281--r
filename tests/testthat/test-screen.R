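mk_meas <- function(well, ratios, valid = TRUE) {
  tibble::tibble(well = well, bead_id = seq_along(ratios), ratio = ratios,
                 valid = valid)
}

test_that("well summaries use the sample SD over valid beads and a bead floor", {
  w <- summarize_wells(mk_meas("B02", rep(0.8, 5)), min_beads = 3)
  expect_equal(w$mean_ratio, 0.8)
  expect_equal(w$sd_ratio, 0)
  expect_true(w$valid)

  w2 <- summarize_wells(mk_meas("B02", c(1.0, 0.8, 1.2)), min_beads = 3)
  expect_equal(w2$mean_ratio, 1.0)
  expect_equal(w2$sd_ratio, 0.2)

  w3 <- summarize_wells(mk_meas("B02", rnorm(10, 1)), min_beads = 50)
  expect_false(w3$valid)
  # invalid beads are excluded from the statistics
  w4 <- summarize_wells(mk_meas("B02", c(1, 1, 99), valid = c(TRUE, TRUE, FALSE)),
                        min_beads = 2)
  expect_equal(w4$mean_ratio, 1)
  expect_equal(w4$n_beads_valid, 2)
})

test_that("control statistics are between-well with CV in percent", {
  lay <- control_plate_layout(3, 0)
  wells <- tibble::tibble(well = lay$well, n_beads_valid = 100,
                          mean_ratio = c(0.9, 1.0, 1.1), sd_ratio = 0.05,
                          valid = TRUE)
  cs <- control_stats(wells, lay, "negative_control")
  expect_equal(cs$mean, 1.0)
  expect_equal(cs$sd, 0.1)
  expect_equal(cs$cv, 10)

  wells$mean_ratio <- rep(1, 3)
  cs0 <- control_stats(wells, lay, "negative_control")
  expect_equal(cs0$sd, 0)
  expect_equal(cs0$cv, 0)

  # an invalid well is dropped with a warning; stats run on the remaining two
  wells$mean_ratio <- c(0.9, 1.1, 5)
  wells$valid <- c(TRUE, TRUE, FALSE)
  expect_warning(cs2 <- control_stats(wells, lay, "negative_control"), "invalid")
  expect_equal(cs2$n_wells, 2)
  expect_equal(cs2$mean, 1.0)

  wells$valid <- c(TRUE, FALSE, FALSE)
  expect_error(suppressWarnings(control_stats(wells, lay, "negative_control")),
               "negative_control")
})

test_that("Z' reproduces the published control statistics of both screens", {
  # focused-library screen: printed Z' = 0.93 from rounded legend inputs
  z1 <- z_prime(list(mean = 0.932, sd = 0.016), list(mean = 0.124, sd = 0.001))
  expect_equal(z1, 1 - 3 * (0.001 + 0.016) / abs(0.124 - 0.932))
  expect_lt(abs(z1 - 0.93), 0.011)
  # prototype screen: printed Z' = 0.69
  z2 <- z_prime(list(mean = 1.009, sd = 0.067), list(mean = 0.288, sd = 0.006))
  expect_lt(abs(z2 - 0.69), 0.011)
  # noiseless limit and undefined case
  expect_equal(z_prime(list(mean = 1, sd = 0), list(mean = 0.2, sd = 0)), 1)
  expect_error(z_prime(list(mean = 1, sd = 0.1), list(mean = 1, sd = 0.1)),
               "undefined")
})

test_that("Z' is invariant under positive scaling and shifts of all values", {
  neg <- c(0.9, 1.0, 1.1, 0.95)
  pos <- c(0.25, 0.3, 0.28, 0.31)
  zp <- function(n, p) z_prime(list(mean = mean(n), sd = sd(n)),
                               list(mean = mean(p), sd = sd(p)))
  base <- zp(neg, pos)
  expect_equal(zp(3.7 * neg, 3.7 * pos), base)
  expect_equal(zp(neg + 11, pos + 11), base)
})

test_that("normalization and percent inhibition follow the control arithmetic", {
  wells <- tibble::tibble(well = c("B02", "C02", "C03"),
                          n_beads_valid = 100, sd_ratio = 0.01, valid = TRUE,
                          mean_ratio = c(1.009, 0.288, 0.124))
  out <- normalize_inhibition(wells, list(mean = 1.009))
  expect_equal(out$percent_inhibition[1], 0)
  expect_equal(out$percent_inhibition[2], 100 * (1 - 0.288 / 1.009),
               tolerance = 1e-12)
  out2 <- normalize_inhibition(wells, list(mean = 0.932))
  expect_equal(out2$percent_inhibition[3], 100 * (1 - 0.124 / 0.932),
               tolerance = 1e-12)
  expect_error(normalize_inhibition(wells, list(mean = 0)), "positive")
})

test_that("hit rules follow the 3xSD and kxCV thresholds", {
  neg <- tibble::tibble(role = "negative_control", n_wells = 5,
                        mean = 1.00, sd = 0.02, cv = 6.70)
  mk <- function(rel) tibble::tibble(well = "C05", valid = TRUE,
                                     relative_ratio = rel,
                                     percent_inhibition = 100 * (1 - rel))
  h <- call_hits(mk(0.50), neg)
  expect_true(h$rule_a_hit)           # 0.50 < 1.00 - 3 * 0.02 = 0.94
  h2 <- call_hits(mk(1.00), neg)
  expect_false(h2$rule_a_hit)
  expect_false(h2$rule_b_hit)
  # rule B threshold: 6 x 6.70% CV = 40.2% inhibition
  expect_false(call_hits(mk(0.61), neg)$rule_b_hit)   # 39% inhibition
  expect_true(call_hits(mk(0.55), neg)$rule_b_hit)    # 45% inhibition
  # ratio-increasing wells are stabilizers, not rule-A hits
  h3 <- call_hits(mk(1.20), neg)
  expect_false(h3$rule_a_hit)
  expect_true(h3$stabilizer)
})

test_that("single-control-well fallback uses bead SD only when permitted", {
  lay <- control_plate_layout(1, 0)
  wells <- tibble::tibble(well = lay$well, n_beads_valid = 100,
                          mean_ratio = 0.9, sd_ratio = 0.09, valid = TRUE)
  expect_error(control_stats(wells, lay, "negative_control"), "at least 2")
  expect_warning(cs <- control_stats(wells, lay, "negative_control",
                                     fallback_bead_sd = TRUE), "between-bead")
  expect_equal(cs$sd_source, "between_bead")
  expect_equal(cs$sd, 0.09)
})
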