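#' Log-linear Munsell-value/carbon pedotransfer model
#'
#' Constructs the pedotransfer model `ln(total carbon) = intercept +
#' slope * Munsell value`, with carbon in g C per kg soil and natural
#' logarithms. Defaults are the packaged continental calibration
#' (intercept 5.07, slope -0.58; r-squared 0.23 over 671 horizons), under
#' which darker (lower-value) soils predict roughly 9-50 g/kg at the surface.
#'
#' @param intercept Intercept on the ln(g/kg) scale.
#' @param slope Change in ln(carbon) per Munsell value unit.
#' @param r_squared,n_obs Fit bookkeeping (optional for hand-built models).
#' @return An object of class `color_carbon_model`.
#' @export
#' @examples
#' m <- color_carbon_model()
#' predict_carbon(4, m)
color_carbon_model <- function(intercept = 5.07, slope = -0.58,
                               r_squared = 0.23, n_obs = 671L) {
  stopifnot(is.finite(intercept), is.finite(slope))
  structure(
    list(intercept = intercept, slope = slope,
         r_squared = r_squared, n_obs = as.integer(n_obs)),
    class = "color_carbon_model"
  )
}

#' @export
print.color_carbon_model <- function(x, ...) {
  cat("Munsell-value/carbon pedotransfer (natural log, g C/kg):\n")
  cat(sprintf("  ln(carbon) = %.4g %+.4g * value", x$intercept, x$slope))
  if (!is.null(x$r_squared) && is.finite(x$r_squared)) {
    cat(sprintf("   (r^2 = %.3g, n = %d)", x$r_squared, x$n_obs))
  }
  cat("\n")
  invisible(x)
}

#' Predict total carbon from Munsell color value
#'
#' Evaluates `exp(intercept + slope * munsell_value)`: strictly positive and,
#' for negative slope, strictly decreasing in value (darker soil, more
#' carbon).
#'
#' @param munsell_value Numeric vector of Munsell color values (warns outside
#'   `[0, 10]`).
#' @param model A [color_carbon_model()].
#' @return Predicted total carbon, g C per kg soil.
#' @export
predict_carbon <- function(munsell_value, model = color_carbon_model()) {
  stopifnot(inherits(model, "color_carbon_model"))
  if (anyNA(munsell_value)) {
    stop("munsell_value contains missing values; use the measured carbon ",
         "for those horizons or drop them", call. = FALSE)
  }
  if (any(munsell_value < 0 | munsell_value > 10)) {
    warning("Munsell value outside [0, 10]; prediction is an extrapolation")
  }
  exp(model$intercept + model$slope * munsell_value)
}

#' Fit the Munsell-value/carbon pedotransfer model
#'
#' Ordinary least squares of `ln(measured carbon)` on Munsell value.
#'
#' @param observations Data frame with columns `munsell_value` and
#'   `carbon_g_kg` (total carbon, g/kg, strictly positive).
#' @return A [color_carbon_model()] carrying the fitted coefficients,
#'   r-squared, `n_obs`, and the underlying `lm` fit as attribute `"fit"`.
#' @export
#' @examples
#' obs <- tibble::tibble(munsell_value = 2:7,
#'                       carbon_g_kg = exp(5.07 - 0.58 * (2:7)))
#' fit_color_carbon_model(obs)
fit_color_carbon_model <- function(observations) {
  stopifnot(all(c("munsell_value", "carbon_g_kg") %in% names(observations)))
  obs <- tibble::as_tibble(observations) |>
    dplyr::filter(!is.na(.data$munsell_value), !is.na(.data$carbon_g_kg))
  if (any(obs$carbon_g_kg <= 0)) {
    stop("carbon_g_kg must be strictly positive (log-linear model)",
         call. = FALSE)
  }
  if (nrow(obs) < 3) {
    stop("need at least 3 complete (munsell_value, carbon) observations",
         call. = FALSE)
  }
  if (dplyr::n_distinct(obs$munsell_value) < 2) {
    stop("all Munsell values identical: degenerate design", call. = FALSE)
  }
  fit <- lm(log(carbon_g_kg) ~ munsell_value, data = obs)
  out <- color_carbon_model(
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    n_obs = nrow(obs)
  )
  attr(out, "fit") <- fit
  out
}

#' Validate a pedotransfer model on held-out color/carbon pairs
#'
#' Predicts carbon for the holdout Munsell values and summarizes the error on
#' the g/kg scale: `bias = mean(observed - predicted)` and RMSE.
#'
#' @param model A [color_carbon_model()].
#' @param holdout Data frame with columns `munsell_value`, `carbon_g_kg`.
#' @return A one-row tibble: `n`, `bias_g_kg`, `rmse_g_kg`.
#' @export
validate_color_model <- function(model, holdout) {
  stopifnot(inherits(model, "color_carbon_model"),
            all(c("munsell_value", "carbon_g_kg") %in% names(holdout)))
  hold <- tibble::as_tibble(holdout) |>
    dplyr::filter(!is.na(.data$munsell_value), !is.na(.data$carbon_g_kg))
  if (nrow(hold) == 0) stop("holdout set is empty", call. = FALSE)
  if (any(hold$carbon_g_kg <= 0)) {
    stop("holdout carbon must be strictly positive", call. = FALSE)
  }
  pred <- predict_carbon(hold$munsell_value, model)
  err <- hold$carbon_g_kg - pred
  tibble::tibble(n = nrow(hold), bias_g_kg = mean(err),
                 rmse_g_kg = sqrt(mean(err^2)))
}

#' @rdname tidy-pedoconverge
#' @method tidy color_carbon_model
#' @export
tidy.color_carbon_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "munsell_value"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname glance-pedoconverge
#' @method glance color_carbon_model
#' @export
glance.color_carbon_model <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n_obs)
}

#' Serialize a pedotransfer model to JSON
#'
#' @param model A [color_carbon_model()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_color_carbon_model <- function(model, path) {
  stopifnot(inherits(model, "color_carbon_model"))
  jsonlite::write_json(
    list(intercept = model$intercept, slope = model$slope,
         r_squared = model$r_squared, n_obs = model$n_obs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_color_carbon_model
#' @export
read_color_carbon_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  color_carbon_model(x$intercept, x$slope, x$r_squared, x$n_obs)
}
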