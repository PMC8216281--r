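#' Read a plate-layout CSV
#'
#' Expected columns: `well,role,compound,concentration_uM`. Roles are
#' canonicalized case-insensitively to `negative_control`,
#' `positive_control`, `compound`. Control rows must leave `compound` and
#' `concentration_uM` empty; compound rows must fill both. Duplicate wells
#' and unknown roles are errors.
#'
#' @param path CSV file.
#' @return Validated layout tibble.
#' @export
read_layout <- function(path) {
  lay <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(), role = readr::col_character(),
    compound = readr::col_character(),
    concentration_uM = readr::col_double()))
  validate_layout(lay)
}

#' Write a plate-layout CSV
#' @param layout Layout tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_layout <- function(layout, path) {
  readr::write_csv(validate_layout(layout), path, na = "")
  invisible(path)
}

validate_layout <- function(layout) {
  req <- c("well", "role", "compound", "concentration_uM")
  missing <- setdiff(req, names(layout))
  if (length(missing)) stop("layout is missing column(s): ", paste(missing, collapse = ", "))
  layout <- tibble::as_tibble(layout)
  layout$role <- tolower(trimws(layout$role))
  roles <- c("negative_control", "positive_control", "compound")
  bad <- setdiff(unique(layout$role), roles)
  if (length(bad)) stop("unknown role(s) in layout: ", paste(bad, collapse = ", "))
  dup <- layout$well[duplicated(layout$well)]
  if (length(dup)) stop("duplicate well(s) in layout: ", paste(unique(dup), collapse = ", "))
  layout$compound[!nzchar(layout$compound %||% "") | is.na(layout$compound)] <- NA_character_
  is_cmp <- layout$role == "compound"
  if (any(is_cmp & (is.na(layout$compound) | is.na(layout$concentration_uM)))) {
    off <- layout$well[is_cmp & (is.na(layout$compound) | is.na(layout$concentration_uM))]
    stop("compound well(s) missing compound id or concentration: ",
         paste(off, collapse = ", "))
  }
  layout
}

#' Read a single-channel grayscale TIFF as an AU matrix
#'
#' 8- or 16-bit grayscale TIFFs are returned as numeric matrices in raw
#' integer counts (AU).
#'
#' @param path TIFF file.
#' @return Numeric matrix.
#' @export
read_bead_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' Write an AU matrix as a 16-bit grayscale TIFF
#'
#' Values are rounded to integer counts and clipped to `[0, 65535]`.
#'
#' @param image Numeric matrix (AU).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bead_image <- function(image, path) {
  img <- pmin(pmax(round(image), 0), 65535) / 65535
  tiff::writeTIFF(img, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Index the image files of a plate directory
#'
#' Parses filenames of the form `{well}_{field}_{channel}.tif` (pattern
#' configurable as a regular expression with three capture groups). Every
#' (well, field) must provide all configured channels; unparseable filenames
#' are skipped with a warning.
#'
#' @param dir Directory containing the TIFFs.
#' @param channels Character vector of required channel names.
#' @param pattern Regex with capture groups for well, field, channel.
#' @return Tibble: `well`, `field`, `channel`, `path`.
#' @export
discover_images <- function(dir, channels = c("FITC", "mCherry"),
                            pattern = "^([A-Za-z]+[0-9]+)_([0-9]+)_(.+)\\.tiff?$") {
  stopifnot(dir.exists(dir))
  files <- list.files(dir, pattern = "\\.tiff?$", ignore.case = TRUE)
  if (length(files) == 0) {
    warning("no TIFF files found in ", dir)
    return(tibble::tibble(well = character(), field = integer(),
                          channel = character(), path = character()))
  }
  m <- stringr::str_match(files, pattern)
  bad <- is.na(m[, 1])
  if (any(bad)) {
    warning("skipping unparseable image filename(s): ",
            paste(files[bad], collapse = ", "))
  }
  idx <- tibble::tibble(well = m[!bad, 2], field = as.integer(m[!bad, 3]),
                        channel = m[!bad, 4],
                        path = file.path(dir, files[!bad]))
  idx <- idx[idx$channel %in% channels, , drop = FALSE]
  chk <- idx |>
    dplyr::group_by(.data$well, .data$field) |>
    dplyr::summarise(missing = paste(setdiff(channels, .data$channel),
                                     collapse = ","), .groups = "drop") |>
    dplyr::filter(nzchar(.data$missing))
  if (nrow(chk) > 0) {
    stop("missing channel(s) for: ",
         paste(sprintf("%s field %d (%s)", chk$well, chk$field, chk$missing),
               collapse = "; "))
  }
  dplyr::arrange(idx, .data$well, .data$field, .data$channel)
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults: channel role
#' mapping, detection, quantification, screening and fitting settings.
#'
#' @param ... Named overrides of top-level entries.
#' @return Nested configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    channels = list(reference = "FITC", signal = "mCherry"),
    detect = list(radius_range_px = c(45, 65), smoothing_sigma_px = 2,
                  threshold = "auto", exclude_border = TRUE,
                  max_overlap_fraction = 0),
    quant = list(angles = c(0, 60, 120), search_window_frac = 0.2,
                 profile_step_px = 0.5, min_peaks = 4,
                 min_reference_intensity = 50, background_margin_px = 10,
                 background_subtract = TRUE, statistic = "peaks"),
    screen = list(min_beads = 50, rule_a_k = 3, rule_b_k = 6,
                  fallback_bead_sd = FALSE),
    fit = list(min_doses = 5, param = "log"),
    seed = 1L,
    fail_on_low_z_prime = FALSE,
    z_prime_floor = 0.5)
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' Unspecified entries fall back to [default_config()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]])) {
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

config_to_params <- function(cfg) {
  list(detect = do.call(detect_params, cfg$detect),
       quant = do.call(quant_params, cfg$quant))
}

#' Write per-bead measurements to CSV
#' @param measurements Per-bead tibble (with `well`, `field` columns).
#' @param path Output CSV.
#' @return Invisibly, `path`.
#' @export
write_bead_csv <- function(measurements, path) {
  readr::write_csv(measurements, path, na = "")
  invisible(path)
}

#' Read a per-bead measurement CSV
#' @param path CSV written by [write_bead_csv()].
#' @return Tibble.
#' @export
read_bead_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(), invalid_reason = readr::col_character(),
    valid = readr::col_logical(), .default = readr::col_double()))
}
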