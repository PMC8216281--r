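#' Summarize per-bead measurements to wells
#'
#' Per well: number of valid beads, mean and sample SD (n - 1) of the
#' protein/RNA ratio across valid beads. A well with fewer than `min_beads`
#' valid beads is marked invalid rather than raising an error, so sparse
#' wells stay visible in the report.
#'
#' @param measurements Tibble of bead measurements with columns `well`,
#'   `ratio`, `valid` (e.g. [measure_field()] output bound across fields with
#'   a `well` column).
#' @param min_beads Minimum valid beads per well.
#' @return Tibble: `well`, `n_beads_valid`, `mean_ratio`, `sd_ratio`, `valid`.
#' @export
summarize_wells <- function(measurements, min_beads = 50) {
  stopifnot(all(c("well", "ratio", "valid") %in% names(measurements)))
  measurements |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(
      n_beads_valid = sum(.data$valid),
      mean_ratio = if (any(.data$valid)) mean(.data$ratio[.data$valid]) else NA_real_,
      sd_ratio = if (sum(.data$valid) >= 2) stats::sd(.data$ratio[.data$valid]) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(valid = .data$n_beads_valid >= min_beads)
}

#' Between-well statistics of a control role
#'
#' Mean, SD and CV across the per-well values of one role. The SD is the
#' between-well sample SD (the replicate-well spread), not the pooled
#' per-bead SD. With a single valid well the between-well SD does not exist;
#' if `fallback_bead_sd = TRUE` the well's between-bead SD stands in and the
#' result is flagged via `sd_source = "between_bead"`, otherwise an error
#' names the role.
#'
#' @param wells Well summaries (from [summarize_wells()], optionally after
#'   [normalize_inhibition()]).
#' @param layout Plate layout tibble (`well`, `role`, ...).
#' @param role Role to summarize.
#' @param value Column of `wells` to use, default `mean_ratio` (use
#'   `"relative_ratio"` after normalization).
#' @param fallback_bead_sd Permit the single-well fallback.
#' @return One-row tibble: `role`, `n_wells`, `mean`, `sd`, `cv` (percent),
#'   `sd_source` (`"between_well"` or `"between_bead"`).
#' @export
control_stats <- function(wells, layout, role, value = "mean_ratio",
                          fallback_bead_sd = FALSE) {
  w <- dplyr::inner_join(wells, layout[, c("well", "role")], by = "well")
  w <- w[w$role == role & w$valid, , drop = FALSE]
  if (nrow(w) == 0) stop("no valid wells with role '", role, "'")
  vals <- w[[value]]
  if (nrow(w) >= 2) {
    m <- mean(vals); s <- stats::sd(vals); src <- "between_well"
  } else if (fallback_bead_sd) {
    warning("only one valid '", role, "' well; using its between-bead SD")
    m <- vals
    s <- w$sd_ratio
    if (value == "relative_ratio" && !is.null(w$mean_ratio)) {
      s <- s * vals / w$mean_ratio  # rescale bead SD onto the relative scale
    }
    src <- "between_bead"
  } else {
    stop("need at least 2 valid wells with role '", role,
         "' for between-well statistics")
  }
  n_invalid <- sum(dplyr::inner_join(wells, layout[, c("well", "role")],
                                     by = "well")$role == role) - nrow(w)
  if (n_invalid > 0) {
    warning(n_invalid, " invalid '", role, "' well(s) excluded from control statistics")
  }
  tibble::tibble(role = role, n_wells = nrow(w), mean = m, sd = s,
                 cv = 100 * s / m, sd_source = src)
}

#' Z' screening-window factor
#'
#' `Z' = 1 - 3 (SD_pos + SD_neg) / |Mean_pos - Mean_neg|`. Values above 0.5
#' indicate an excellent separation between negative and positive controls;
#' the noiseless limit is 1.
#'
#' @param neg,pos Control statistics: any list / one-row data frame carrying
#'   `mean` and `sd` (e.g. [control_stats()] output).
#' @return Scalar Z' (always <= 1).
#' @export
z_prime <- function(neg, pos) {
  mn <- neg$mean[1]; mp <- pos$mean[1]
  sn <- neg$sd[1]; sp <- pos$sd[1]
  stopifnot(is.finite(mn), is.finite(mp), sn >= 0, sp >= 0)
  if (mp == mn) stop("Z' is undefined when the control means are equal")
  1 - 3 * (sp + sn) / abs(mp - mn)
}

#' Normalize wells to the negative-control mean and add percent inhibition
#'
#' `relative_ratio = mean_ratio / neg$mean`;
#' `percent_inhibition = 100 * (1 - relative_ratio)` (negative for
#' stabilizers that increase the ratio).
#'
#' @param wells Well summaries.
#' @param neg Negative-control statistics on the `mean_ratio` scale.
#' @return `wells` with `relative_ratio` and `percent_inhibition` columns.
#' @export
normalize_inhibition <- function(wells, neg) {
  if (!is.finite(neg$mean[1]) || neg$mean[1] <= 0) {
    stop("cannot normalize: negative-control mean must be positive")
  }
  dplyr::mutate(wells,
                relative_ratio = .data$mean_ratio / neg$mean[1],
                percent_inhibition = 100 * (1 - .data$relative_ratio))
}

#' Call inhibitor hits by the two screening rules
#'
#' Rule A (3 x SD): a well is a hit when its relative ratio falls below the
#' negative-control mean minus `rule_a_k` between-well SDs. Rule B (k x CV):
#' a hit when its percent inhibition exceeds `rule_b_k` times the
#' negative-control CV (e.g. a 6.7% CV and k = 6 give a 40.2% inhibition
#' threshold). Wells above the symmetric upper band are flagged separately as
#' stabilizers; the screen itself targets inhibitors.
#'
#' @param wells Normalized well summaries (after [normalize_inhibition()]).
#' @param neg Negative-control statistics **on the relative-ratio scale**
#'   (`control_stats(..., value = "relative_ratio")`).
#' @param layout Optional layout to carry `role`, `compound`,
#'   `concentration_uM` into the result.
#' @param rule_a_k,rule_b_k Rule multipliers.
#' @return Tibble: well columns plus `rule_a_hit`, `rule_b_hit`, `stabilizer`.
#' @export
call_hits <- function(wells, neg, layout = NULL, rule_a_k = 3, rule_b_k = 6) {
  stopifnot(all(c("relative_ratio", "percent_inhibition") %in% names(wells)))
  lower <- neg$mean[1] - rule_a_k * neg$sd[1]
  upper <- neg$mean[1] + rule_a_k * neg$sd[1]
  thr_b <- rule_b_k * neg$cv[1]
  out <- dplyr::mutate(wells,
                       rule_a_hit = .data$valid & .data$relative_ratio < lower,
                       rule_b_hit = .data$valid & .data$percent_inhibition > thr_b,
                       stabilizer = .data$valid & .data$relative_ratio > upper)
  if (!is.null(layout)) {
    out <- dplyr::left_join(
      out, layout[, intersect(c("well", "role", "compound", "concentration_uM"),
                              names(layout))], by = "well") |>
      dplyr::relocate(dplyr::any_of(c("role", "compound", "concentration_uM")),
                      .after = "well")
  }
  out
}

#' Full plate-level screening analysis
#'
#' Runs the well-level screening chain: control statistics on the raw ratio
#' scale, normalization to the negative-control mean, control statistics on
#' the relative scale, Z', and both hit rules.
#'
#' @param measurements Per-bead measurements with a `well` column.
#' @param layout Plate layout.
#' @param min_beads Per-well valid-bead floor.
#' @param rule_a_k,rule_b_k Hit-rule multipliers.
#' @param fallback_bead_sd Allow single-control-well SD fallback.
#' @return List: `wells` (normalized summaries with hit calls), `neg`, `pos`
#'   (relative-scale control stats), `z_prime`.
#' @export
screen_plate <- function(measurements, layout, min_beads = 50,
                         rule_a_k = 3, rule_b_k = 6, fallback_bead_sd = FALSE) {
  wells <- summarize_wells(measurements, min_beads = min_beads)
  neg_raw <- control_stats(wells, layout, "negative_control",
                           fallback_bead_sd = fallback_bead_sd)
  wells <- normalize_inhibition(wells, neg_raw)
  neg <- control_stats(wells, layout, "negative_control",
                       value = "relative_ratio",
                       fallback_bead_sd = fallback_bead_sd)
  pos <- control_stats(wells, layout, "positive_control",
                       value = "relative_ratio",
                       fallback_bead_sd = fallback_bead_sd)
  zp <- z_prime(neg, pos)
  hits <- call_hits(wells, neg, layout, rule_a_k = rule_a_k, rule_b_k = rule_b_k)
  list(wells = hits, neg = neg, pos = pos, z_prime = zp)
}
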