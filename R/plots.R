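#' Scatter plot of an MR fit
#'
#' Outcome effects against exposure effects (instruments oriented so the
#' exposure effect is positive), with one fitted line per estimator:
#' through the origin for IVW and the weighted median, with intercept
#' for MR-Egger.
#'
#' @param object An `mr_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, ...) {
  d <- object$instruments
  flip <- d$beta_exposure < 0
  pts <- tibble::tibble(
    bx = abs(d$beta_exposure),
    by = ifelse(flip, -d$beta_outcome, d$beta_outcome),
    se = d$se_outcome
  )
  lines <- dplyr::mutate(
    dplyr::filter(object$estimates, .data$method != "egger_intercept"),
    intercept = 0
  )
  icpt <- dplyr::filter(object$estimates, .data$method == "egger_intercept")
  if (nrow(icpt) == 1 && "egger_slope" %in% lines$method) {
    lines$intercept[lines$method == "egger_slope"] <- icpt$beta
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$se,
                                        ymax = .data$by + .data$se),
                           width = 0, colour = "grey70") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(slope = .data$beta, intercept = .data$intercept,
                   colour = .data$method)) +
    ggplot2::labs(
      x = "Effect on exposure (mmHg per allele)",
      y = "Effect on outcome (log-odds per allele)",
      colour = "Estimator",
      title = if (!is.na(object$exposure))
        paste(object$exposure, "→", object$outcome) else NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of per-10-mmHg odds ratios
#'
#' One row per trait (or drug class) and method, with 95% confidence
#' intervals, on a log-scaled odds-ratio axis.
#'
#' @param estimates Tidy estimate tibble: either a primary report's
#'   `estimates` (columns `exposure`, `method`, `or_per_10`,
#'   `ci_or_low_10`, `ci_or_high_10`) or a drug report's (columns
#'   `drug_class`, `route`, `method`, `or_per_10_decrease`, `ci_or_low`,
#'   `ci_or_high`).
#' @return A ggplot object.
#' @export
plot_mr_forest <- function(estimates) {
  e <- tibble::as_tibble(estimates)
  if ("or_per_10_decrease" %in% names(e)) {
    d <- dplyr::transmute(
      dplyr::filter(e, .data$assessable),
      label = paste(.data$drug_class, .data$route, .data$method),
      or = .data$or_per_10_decrease,
      lo = .data$ci_or_low, hi = .data$ci_or_high)
    xlab <- "OR per 10-mmHg SBP decrease (95% CI)"
  } else {
    d <- dplyr::transmute(
      dplyr::filter(e, !is.na(.data$or_per_10)),
      label = paste(.data$exposure, .data$method),
      or = .data$or_per_10,
      lo = .data$ci_or_low_10, hi = .data$ci_or_high_10)
    xlab <- "OR per 10-mmHg increase (95% CI)"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo,
                                         xmax = .data$hi), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}
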