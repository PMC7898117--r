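#' Plot a converged urban soil profile
#'
#' Points of convergence by depth (depth increasing downward, property on a
#' log axis), optionally overlaid with a fitted profile model.
#'
#' @param object A `converged_profile`.
#' @param model Optional `polynomial_profile` or `exponential_profile` whose
#'   predictions are drawn as a line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot converged_profile
#' @export
autoplot.converged_profile <- function(object, model = NULL, ...) {
  df <- tibble::as_tibble(object)
  prop <- attr(object, "property")
  lab <- if (identical(prop, "carbon_g_per_kg")) {
    "converged carbon (g C/kg)"
  } else "converged particle size (mm)"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$point,
                                        y = .data$depth_cm)) +
    ggplot2::geom_point(alpha = 0.5, na.rm = TRUE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = lab, y = "depth (cm)") +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    grid <- tibble::tibble(depth_cm = seq(min(df$depth_cm),
                                          max(df$depth_cm), by = 1))
    grid$pred <- predict(model, grid$depth_cm)
    p <- p + ggplot2::geom_path(data = grid,
                                ggplot2::aes(x = .data$pred,
                                             y = .data$depth_cm),
                                color = "firebrick", linewidth = 0.8)
  }
  p
}

#' Plot a whole-profile IPA convergence regression
#'
#' Log urban:reference IPA ratio against log reference IPA with the fitted
#' line; the horizontal line at 0 marks a ratio of 1 and its crossing with
#' the fit is the converged IPA.
#'
#' @param object An `ipa_convergence` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ipa_convergence
#' @export
autoplot.ipa_convergence <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ln_ref, y = .data$ln_ratio)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         color = "firebrick") +
    ggplot2::labs(x = "ln(reference IPA)",
                  y = "ln(urban IPA / reference IPA)",
                  title = paste0(object$property, ": converged IPA = ",
                                 signif(object$converged_ipa, 3))) +
    ggplot2::theme_minimal()
}

#' Plot urban-minus-reference differences at stated depths
#'
#' @param diffs Output of [depth_differences()].
#' @param property Label for the x axis.
#' @return A ggplot object.
#' @export
plot_depth_differences <- function(diffs, property = "property") {
  ggplot2::ggplot(dplyr::filter(diffs, !is.na(.data$difference)),
                  ggplot2::aes(x = .data$difference)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~ .data$depth_cm, labeller = ggplot2::label_both) +
    ggplot2::labs(x = paste("urban - reference", property), y = "pairs") +
    ggplot2::theme_minimal()
}
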