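#' Run the full screening pipeline on a plate directory
#'
#' Executes detection on the reference channel, ring quantification on every
#' channel, well aggregation, plate QC (Z', control CVs), hit calling, and --
#' for every compound with at least `fit$min_doses` distinct concentrations
#' -- a 4PL IC50 fit. Writes `beads.csv`, `wells.csv`, `qc.json`,
#' `fits.json`, `curves.csv` (when fits exist) and `run.log` under
#' `out_dir`. Reruns with identical inputs produce byte-identical tables.
#'
#' @param image_dir Directory of `{well}_{field}_{channel}.tif` images.
#' @param layout Plate-layout tibble or path to a layout CSV.
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list, see [default_config()].
#' @return Invisibly, a list with `beads`, `wells`, `qc`
#'   (`z_prime`, `neg`, `pos`), `fits`.
#' @export
run_pipeline <- function(image_dir, layout, out_dir, config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  if (is.character(layout)) layout <- read_layout(layout)
  layout <- validate_layout(layout)
  prm <- config_to_params(config)
  ref <- config$channels$reference
  sig <- config$channels$signal
  channels <- c(ref, sig)
  say("pipeline start: reference=%s signal=%s seed=%s", ref, sig, config$seed)

  idx <- discover_images(image_dir, channels = channels)
  say("indexed %d images over %d (well, field) pairs", nrow(idx),
      nrow(dplyr::distinct(idx, .data$well, .data$field)))

  pairs <- dplyr::distinct(idx, .data$well, .data$field)
  beads <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    w <- pairs$well[i]; f <- pairs$field[i]
    sel <- idx[idx$well == w & idx$field == f, ]
    imgs <- stats::setNames(lapply(sel$path, read_bead_image), sel$channel)
    loci <- detect_beads(imgs[[ref]], prm$detect)
    say("%s field %d: %d loci (%d clean)", w, f, nrow(loci),
        sum(is_clean_locus(loci)))
    meas <- measure_field(imgs, loci, reference_channel = ref,
                          signal_channel = sig, params = prm$quant)
    if (nrow(meas)) dplyr::mutate(meas, well = w, field = f, .before = 1) else meas
  })
  if (nrow(beads) == 0) stop("no measurable beads found on the plate")
  write_bead_csv(beads, file.path(out_dir, "beads.csv"))

  scr <- screen_plate(beads, layout,
                      min_beads = config$screen$min_beads,
                      rule_a_k = config$screen$rule_a_k,
                      rule_b_k = config$screen$rule_b_k,
                      fallback_bead_sd = config$screen$fallback_bead_sd)
  say("Z' = %.3f (neg CV %.2f%%, pos CV %.2f%%)", scr$z_prime,
      scr$neg$cv, scr$pos$cv)
  readr::write_csv(scr$wells, file.path(out_dir, "wells.csv"), na = "")
  qc <- list(z_prime = scr$z_prime,
             negative_control = as.list(scr$neg),
             positive_control = as.list(scr$pos),
             sd_fallback_used = any(c(scr$neg$sd_source, scr$pos$sd_source) ==
                                      "between_bead"))
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  fits <- fit_plate_compounds(scr$wells, min_doses = config$fit$min_doses,
                              param = config$fit$param)
  if (length(fits)) {
    fit_json <- lapply(fits, function(f) {
      g <- glance(f)
      list(coefficients = tidy(f), ic50 = g$ic50, ic50_se = g$ic50_se,
           rss = g$rss, converged = g$converged, reliable = g$reliable)
    })
    jsonlite::write_json(fit_json, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    curves <- purrr::imap_dfr(fits, function(f, cmp) {
      if (!f$converged) return(NULL)
      xs <- exp(seq(log(max(min(f$data$x[f$data$x > 0]), 1e-6)),
                    log(max(f$data$x)), length.out = 50))
      tibble::tibble(compound = cmp, concentration_uM = xs,
                     predicted = predict_4pl(f, xs))
    })
    readr::write_csv(curves, file.path(out_dir, "curves.csv"))
    say("fitted %d compound dose-response curve(s)", length(fits))
  }
  writeLines(log_lines, log_path)
  if (isTRUE(config$fail_on_low_z_prime) && scr$z_prime < config$z_prime_floor) {
    stop("plate failed QC: Z' = ", round(scr$z_prime, 3), " < ",
         config$z_prime_floor)
  }
  invisible(list(beads = beads, wells = scr$wells,
                 qc = list(z_prime = scr$z_prime, neg = scr$neg, pos = scr$pos),
                 fits = fits))
}

# One 4PL fit per compound with enough distinct doses.
fit_plate_compounds <- function(wells, min_doses = 5, param = "log") {
  if (!"compound" %in% names(wells)) return(list())
  cmp <- wells[!is.na(wells$compound) & wells$valid, ]
  if (nrow(cmp) == 0) return(list())
  out <- list()
  for (id in unique(cmp$compound)) {
    d <- cmp[cmp$compound == id, ]
    if (length(unique(d$concentration_uM)) < min_doses) next
    out[[id]] <- fit_4pl(data.frame(dose = d$concentration_uM,
                                    response = d$relative_ratio),
                         param = param)
  }
  out
}
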