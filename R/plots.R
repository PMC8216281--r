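#' Plot a fitted concentration-response curve
#'
#' Points are the observed responses; the line is the fitted 4PL evaluated on
#' a log-spaced dose grid; a dashed vertical marks the IC50.
#'
#' @param object A `cona_4pl` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cona_4pl
#' @export
autoplot.cona_4pl <- function(object, ...) {
  stopifnot(object$converged)
  d <- object$data[object$data$x > 0, ]
  xs <- exp(seq(log(min(d$x)), log(max(d$x)), length.out = 100))
  curve <- data.frame(x = xs, y = predict_4pl(object, xs))
  ic50 <- coef_4pl(object)[["ic50"]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, color = "#c0392b") +
    ggplot2::geom_vline(xintercept = ic50, linetype = "dashed", color = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)", y = "relative ratio",
                  title = sprintf("4PL fit: IC50 = %.3g uM", ic50)) +
    ggplot2::theme_minimal()
}

#' Plot a screening plate: per-well relative ratios with hit thresholds
#'
#' Horizontal lines mark the negative-control mean and the mean minus
#' `rule_a_k` between-well SDs (the rule-A hit threshold). Wells are colored
#' by role; rule-A hits are highlighted.
#'
#' @param wells Wells with hit calls ([screen_plate()] `$wells`).
#' @param neg Negative-control stats on the relative scale.
#' @param rule_a_k Rule-A multiplier used for the threshold line.
#' @return A ggplot.
#' @export
plot_screen <- function(wells, neg, rule_a_k = 3) {
  w <- dplyr::mutate(wells, idx = dplyr::row_number())
  ggplot2::ggplot(w, ggplot2::aes(x = .data$idx, y = .data$relative_ratio)) +
    ggplot2::geom_hline(yintercept = neg$mean[1], color = "black") +
    ggplot2::geom_hline(yintercept = neg$mean[1] - rule_a_k * neg$sd[1],
                        color = "black", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(color = .data$rule_a_hit), size = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "#c0392b"),
                                name = "rule-A hit") +
    ggplot2::labs(x = "well", y = "relative protein/RNA ring ratio") +
    ggplot2::theme_minimal()
}

#' Plot chord intensity profiles of one bead
#'
#' One panel per chord angle; vertical dashed lines mark `+/- radius`.
#'
#' @param profiles A `cona_profiles` from [extract_profiles()].
#' @return A ggplot.
#' @export
plot_profiles <- function(profiles) {
  R <- profiles$radius_px
  ggplot2::ggplot(profiles$profiles,
                  ggplot2::aes(x = .data$t, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(-R, R), linetype = "dashed",
                        color = "grey50") +
    ggplot2::facet_wrap(~angle, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position along chord (px)", y = "intensity (AU)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
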