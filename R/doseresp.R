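#' Fit a four-parameter logistic concentration-response curve
#'
#' Nonlinear least-squares fit of the 4PL model
#' \deqn{y = bottom + (top - bottom) / (1 + (x / IC50)^{hill})}
#' to well-level relative ratios versus inhibitor dose (uM). The IC50 is the
#' inflection dose of the fitted curve (relative IC50). Fitting uses the
#' Levenberg-Marquardt algorithm; the IC50 enters the optimization either as
#' `log(IC50)` (default, numerically better conditioned for log-spaced doses)
#' or directly -- both parameterizations recover the same optimum on clean
#' data. Standard errors come from the local curvature of the least-squares
#' objective at the optimum (the usual asymptotic covariance); the IC50 SE
#' under the log parameterization is mapped back by the delta method.
#'
#' Default starting values: `top` = max response, `bottom` = min response,
#' `ic50` = geometric mean of the doses bracketing the half response,
#' `hill` = 1.
#'
#' @param data Data frame of dose-response points.
#' @param dose,response Column names (tidy-eval) holding dose (uM) and
#'   response; defaults `dose`, `response`.
#' @param init Optional named list overriding starting values
#'   (`top`, `bottom`, `ic50`, `hill`).
#' @param param `"log"` or `"linear"` IC50 parameterization.
#' @return A `cona_4pl` object with elements `coefficients` (tibble `term`,
#'   `estimate`, `std_error`), `rss`, `df_residual`, `converged`, `reliable`
#'   (`FALSE` when `SE(IC50) > IC50`, an unidentifiable transition), `data`,
#'   plus [generics::tidy()], [generics::glance()], `predict()` and
#'   [ggplot2::autoplot()] methods.
#' @export
fit_4pl <- function(data, dose = "dose", response = "response",
                    init = NULL, param = c("log", "linear")) {
  param <- match.arg(param)
  dose_col <- if (is.character(dose)) dose else rlang::as_name(rlang::enquo(dose))
  resp_col <- if (is.character(response)) response else rlang::as_name(rlang::enquo(response))
  x <- data[[dose_col]]; y <- data[[resp_col]]
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(x)), all(is.finite(y)),
            all(x >= 0))
  if (length(unique(x)) < 2) stop("doses are all equal; cannot fit a dose-response curve")
  if (length(unique(x)) < 5) {
    warning("fewer than 5 distinct doses; the 4PL transition may be poorly constrained")
  }
  start <- start_4pl(x, y, init)
  df <- data.frame(x = x, y = y)
  if (param == "log") {
    st <- c(top = start$top, bottom = start$bottom,
            lic50 = log(start$ic50), hill = start$hill)
  } else {
    st <- c(top = start$top, bottom = start$bottom,
            ic50 = start$ic50, hill = start$hill)
  }
  model <- function(p) {
    ic50 <- if (param == "log") exp(p[["lic50"]]) else p[["ic50"]]
    four_pl(x, p[["top"]], p[["bottom"]], ic50, p[["hill"]])
  }
  # analytic Jacobian of the residuals y - model(p): finite-difference steps
  # degenerate when a parameter (e.g. log IC50 near 0) sits close to zero
  jac <- function(p) four_pl_jacobian(x, p, param)
  diag_msg <- NA_character_
  res <- tryCatch(
    minpack.lm::nls.lm(par = st, fn = function(p) y - model(p), jac = jac,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) { diag_msg <<- conditionMessage(e); NULL })
  conv <- !is.null(res) && res$info %in% 1:3
  if (is.null(res)) {
    return(structure(list(coefficients = NULL, rss = NA_real_,
                          df_residual = NA_integer_, converged = FALSE,
                          reliable = FALSE, diagnostics = diag_msg,
                          param = param, data = df),
                     class = "cona_4pl"))
  }
  est <- res$par
  se <- tryCatch(summary(res)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, length(est)), names(est)))
  if (param == "log") {
    ic50 <- exp(est[["lic50"]])
    se_ic50 <- ic50 * se[["lic50"]]  # delta method
    est <- c(top = est[["top"]], bottom = est[["bottom"]],
             ic50 = ic50, hill = est[["hill"]])
    se <- c(top = se[["top"]], bottom = se[["bottom"]],
            ic50 = se_ic50, hill = se[["hill"]])
  } else {
    est <- est[c("top", "bottom", "ic50", "hill")]
    se <- se[c("top", "bottom", "ic50", "hill")]
  }
  # the IC50 is only trustworthy when some dose actually samples the
  # transition; a pure two-level jump fits arbitrarily steep curves
  fitted <- four_pl(x, est[["top"]], est[["bottom"]], est[["ic50"]],
                    est[["hill"]])
  span <- est[["top"]] - est[["bottom"]]
  frac <- if (span > 0) (fitted - est[["bottom"]]) / span else rep(0, length(x))
  samples_transition <- any(frac > 0.2 & frac < 0.8)
  reliable <- conv && is.finite(se[["ic50"]]) &&
    se[["ic50"]] <= est[["ic50"]] && samples_transition
  structure(list(
    coefficients = tibble::tibble(term = names(est),
                                  estimate = unname(est),
                                  std_error = unname(se)),
    rss = res$deviance,
    df_residual = length(y) - length(est),
    converged = conv, reliable = reliable,
    diagnostics = if (conv) NA_character_ else res$message,
    param = param, fit = res, data = df),
    class = "cona_4pl")
}

# Jacobian of the residuals (y - model) wrt the 4PL parameters.
four_pl_jacobian <- function(x, p, param) {
  top <- p[["top"]]; bottom <- p[["bottom"]]; hill <- p[["hill"]]
  ic50 <- if (param == "log") exp(p[["lic50"]]) else p[["ic50"]]
  u <- ifelse(x > 0, (x / ic50)^hill, 0)
  inv <- 1 / (1 + u)
  d_top <- inv
  d_bottom <- u * inv
  d_u <- -(top - bottom) * inv^2
  du_hill <- ifelse(x > 0, u * log(x / ic50), 0)
  du_scale <- if (param == "log") -hill * u else -hill * u / ic50
  J <- cbind(top = d_top, bottom = d_bottom,
             scale = d_u * du_scale, hill = d_u * du_hill)
  colnames(J) <- c("top", "bottom", if (param == "log") "lic50" else "ic50",
                   "hill")
  -J[, names(p), drop = FALSE]
}

start_4pl <- function(x, y, init = NULL) {
  top <- max(y); bottom <- min(y)
  half <- (top + bottom) / 2
  agg <- stats::aggregate(y, list(x = x), mean)
  agg <- agg[order(agg$x), ]
  ic50 <- NA_real_
  for (i in seq_len(nrow(agg) - 1)) {
    d1 <- agg$x[i]; d2 <- agg$x[i + 1]
    if (d1 > 0 && d2 > 0 &&
        (agg[i, 2] - half) * (agg[i + 1, 2] - half) <= 0) {
      ic50 <- sqrt(d1 * d2)  # geometric mean of the bracketing doses
      break
    }
  }
  if (!is.finite(ic50) || ic50 <= 0) {
    pos <- agg$x[agg$x > 0]
    ic50 <- exp(mean(log(pos)))
  }
  st <- list(top = top, bottom = bottom, ic50 = ic50, hill = 1)
  if (!is.null(init)) st[names(init)] <- init
  st
}

#' Evaluate a fitted 4PL curve
#'
#' @param fit A `cona_4pl` object (or a named list with `top`, `bottom`,
#'   `ic50`, `hill`).
#' @param x Dose(s), uM (>= 0; `x = 0` returns `top`, `x = ic50` the
#'   midpoint `(top + bottom) / 2`).
#' @return Predicted response(s).
#' @export
predict_4pl <- function(fit, x) {
  p <- coef_4pl(fit)
  four_pl(x, p[["top"]], p[["bottom"]], p[["ic50"]], p[["hill"]])
}

coef_4pl <- function(fit) {
  if (inherits(fit, "cona_4pl")) {
    if (is.null(fit$coefficients)) stop("fit did not converge; no coefficients")
    stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  } else unlist(fit[c("top", "bottom", "ic50", "hill")])
}

#' @export
predict.cona_4pl <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
  else if (is.data.frame(newdata)) newdata[[1]] else newdata
  predict_4pl(object, x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a 4PL fit into one row per parameter
#' @param x A `cona_4pl` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`.
#' @method tidy cona_4pl
#' @export
tidy.cona_4pl <- function(x, ...) {
  if (is.null(x$coefficients)) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std_error = numeric()))
  }
  x$coefficients
}

#' One-row model summary of a 4PL fit
#' @param x A `cona_4pl` object.
#' @param ... Unused.
#' @return Tibble with `ic50`, `ic50_se`, `hill`, `rss`, `df_residual`,
#'   `converged`, `reliable`.
#' @method glance cona_4pl
#' @export
glance.cona_4pl <- function(x, ...) {
  cf <- if (is.null(x$coefficients)) {
    c(ic50 = NA_real_, hill = NA_real_)
  } else stats::setNames(x$coefficients$estimate, x$coefficients$term)
  se <- if (is.null(x$coefficients)) c(ic50 = NA_real_)
  else stats::setNames(x$coefficients$std_error, x$coefficients$term)
  tibble::tibble(ic50 = unname(cf[["ic50"]]),
                 ic50_se = unname(se[["ic50"]]),
                 hill = unname(cf[["hill"]]),
                 rss = x$rss, df_residual = x$df_residual,
                 converged = x$converged, reliable = x$reliable)
}

#' @export
print.cona_4pl <- function(x, ...) {
  if (!x$converged) {
    cat("<4PL fit: not converged>", if (!is.na(x$diagnostics)) x$diagnostics, "\n")
    return(invisible(x))
  }
  cf <- stats::setNames(x$coefficients$estimate, x$coefficients$term)
  se <- stats::setNames(x$coefficients$std_error, x$coefficients$term)
  cat(sprintf("<4PL fit: IC50 %.3g +/- %.2g uM, hill %.3g, top %.3g, bottom %.3g%s>\n",
              cf["ic50"], se["ic50"], cf["hill"], cf["top"], cf["bottom"],
              if (x$reliable) "" else " [unreliable]"))
  invisible(x)
}
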