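#' Per-slice urban:reference ratio table
#'
#' For every pair and every 1-cm depth slice where both members have a
#' positive value, computes the natural-log reference value and the
#' natural-log urban-to-reference ratio — the rows fed to the per-depth
#' convergence regressions. Slices where either member is missing or
#' non-positive are excluded pairwise; the number of excluded rows is
#' attached as attribute `"n_excluded"`.
#'
#' @param sliced Sliced-profile tibble from [slice_profiles()] covering both
#'   members of every pair, one property.
#' @param pairs Pairing tibble (`urban_pedon_id`, `reference_pedon_id`).
#' @return A tibble with columns `depth_cm`, `urban_pedon_id`,
#'   `reference_pedon_id`, `property`, `ln_reference`, `ln_ratio`.
#' @export
slice_ratio_table <- function(sliced, pairs) {
  stopifnot(all(c("pedon_id", "property", "depth_cm", "value") %in%
                  names(sliced)))
  prop <- unique(sliced$property)
  if (length(prop) != 1) {
    stop("slice_ratio_table expects a single property, got: ",
         paste(prop, collapse = ", "), call. = FALSE)
  }
  urb <- sliced |>
    dplyr::select(urban_pedon_id = "pedon_id", "depth_cm",
                  urban_value = "value")
  ref <- sliced |>
    dplyr::select(reference_pedon_id = "pedon_id", "depth_cm",
                  reference_value = "value")
  joined <- tibble::as_tibble(pairs) |>
    dplyr::select("urban_pedon_id", "reference_pedon_id") |>
    dplyr::inner_join(urb, by = "urban_pedon_id",
                      relationship = "many-to-many") |>
    dplyr::inner_join(ref, by = c("reference_pedon_id", "depth_cm"))
  usable <- !is.na(joined$urban_value) & !is.na(joined$reference_value) &
    joined$urban_value > 0 & joined$reference_value > 0
  out <- joined[usable, ] |>
    dplyr::transmute(
      .data$depth_cm, .data$urban_pedon_id, .data$reference_pedon_id,
      property = prop,
      ln_reference = log(.data$reference_value),
      ln_ratio = log(.data$urban_value) - log(.data$reference_value)
    )
  attr(out, "n_excluded") <- sum(!usable)
  out
}

#' Point of convergence of a fitted ratio regression
#'
#' Given the log-log regression `ln(urban/reference) = intercept +
#' slope * ln(reference)`, the point of convergence is the reference level at
#' which the fitted urban:reference ratio equals 1:
#' `exp(-intercept / slope)`. For negative slope, reference levels below the
#' point have fitted ratios above 1 and levels above it ratios below 1 —
#' urbanization pulls the property toward the point from both sides.
#'
#' @param intercept,slope Regression coefficients (natural logs). Vectorized.
#' @return The point of convergence in the property's units.
#' @export
#' @examples
#' convergence_point(3.15, -0.81)
convergence_point <- function(intercept, slope) {
  if (any(slope == 0, na.rm = TRUE)) {
    stop("slope is 0: the fitted ratio never crosses 1, the point of ",
         "convergence is undefined", call. = FALSE)
  }
  exp(-intercept / slope)
}

#' Fit per-depth convergence regressions
#'
#' For each 1-cm depth slice, ordinary least squares of the log
#' urban:reference ratio (response) on the log reference value (predictor),
#' pooled over all pairs. Depths with fewer than 3 usable pairs or a
#' degenerate design (all reference values equal) are flagged and left
#' unfitted rather than dropped. Raw slope p-values are reported alongside
#' Benjamini-Hochberg adjusted values across the fitted depths. The point of
#' convergence `exp(-intercept/slope)` is extracted wherever the slope is
#' nonzero.
#'
#' @param ratio_rows Output of [slice_ratio_table()].
#' @param direction `"ratio_on_reference"` (default; response is the log
#'   ratio) or `"reference_on_ratio"` (transposed fit, in which case the
#'   point of convergence is `exp(intercept)`).
#' @return A tibble with one row per depth: `depth_cm`, `property`,
#'   `n_pairs`, `intercept`, `slope`, `r_squared`, `p_value`, `p_bh`,
#'   `convergence_point`, `fitted` (FALSE where flagged), `flag`.
#' @export
fit_slice_regressions <- function(ratio_rows,
                                  direction = c("ratio_on_reference",
                                                "reference_on_ratio")) {
  direction <- match.arg(direction)
  stopifnot(all(c("depth_cm", "ln_reference", "ln_ratio") %in%
                  names(ratio_rows)))
  prop <- if ("property" %in% names(ratio_rows) && nrow(ratio_rows)) {
    ratio_rows$property[1]
  } else NA_character_
  one <- function(df) {
    base <- tibble::tibble(
      n_pairs = nrow(df), intercept = NA_real_, slope = NA_real_,
      r_squared = NA_real_, p_value = NA_real_,
      convergence_point = NA_real_, fitted = FALSE, flag = NA_character_
    )
    if (nrow(df) < 3) {
      base$flag <- "fewer than 3 usable pairs"
      return(base)
    }
    if (dplyr::n_distinct(df$ln_reference) < 2) {
      base$flag <- "degenerate design: all reference values equal"
      return(base)
    }
    fit <- if (direction == "ratio_on_reference") {
      lm(ln_ratio ~ ln_reference, data = df)
    } else {
      lm(ln_reference ~ ln_ratio, data = df)
    }
    sm <- summary(fit)
    cf <- coef(fit)
    base$intercept <- unname(cf[1])
    base$slope <- unname(cf[2])
    base$r_squared <- sm$r.squared
    base$p_value <- if (nrow(sm$coefficients) > 1 &&
                        ncol(sm$coefficients) >= 4) {
      sm$coefficients[2, 4]
    } else NA_real_
    base$fitted <- TRUE
    cp <- if (direction == "ratio_on_reference") {
      if (base$slope != 0) exp(-base$intercept / base$slope) else NA_real_
    } else {
      exp(base$intercept)
    }
    if (direction == "ratio_on_reference" && base$slope == 0) {
      base$flag <- "slope 0: convergence point undefined"
    }
    base$convergence_point <- cp
    base
  }
  out <- tibble::as_tibble(ratio_rows) |>
    dplyr::group_by(.data$depth_cm) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup() |>
    dplyr::mutate(property = prop, .after = "depth_cm")
  out$p_bh <- NA_real_
  out$p_bh[out$fitted] <- p.adjust(out$p_value[out$fitted], method = "BH")
  dplyr::relocate(out, "p_bh", .after = "p_value")
}

#' Assemble a converged urban soil profile
#'
#' Stacks the per-depth points of convergence into a depth profile — the
#' "universal urban soil profile" the per-slice regressions imply. Depths
#' whose regression was flagged or produced no defined point are left
#' missing.
#'
#' @param slice_fits Output of [fit_slice_regressions()].
#' @param property Property name; defaults to the one carried by
#'   `slice_fits`.
#' @return An object of class `converged_profile`: a tibble `depth_cm`,
#'   `point`, with the property name as attribute `"property"`.
#' @export
build_converged_profile <- function(slice_fits, property = NULL) {
  stopifnot(all(c("depth_cm", "convergence_point") %in% names(slice_fits)))
  if (is.null(property)) property <- slice_fits$property[1]
  pts <- tibble::tibble(depth_cm = slice_fits$depth_cm,
                        point = slice_fits$convergence_point)
  n_def <- sum(!is.na(pts$point))
  if (n_def < 10) {
    stop("only ", n_def, " depths have a defined point of convergence; ",
         "at least 10 required to build a profile", call. = FALSE)
  }
  if (any(pts$point <= 0, na.rm = TRUE)) {
    stop("non-positive convergence point encountered", call. = FALSE)
  }
  structure(pts, property = property, class = c("converged_profile",
                                                class(pts)))
}

#' Fit the quartic particle-size profile model
#'
#' Least-squares fourth-order polynomial of `ln(particle size)` on depth,
#' using an orthogonalized, scaled depth basis (`stats::poly`). The basis is
#' recorded in the returned object so predictions are reproducible;
#' coefficients are reported on that basis, not on raw depth powers.
#'
#' @param converged A `converged_profile` of particle size, from
#'   [build_converged_profile()].
#' @param degree Polynomial degree (default 4).
#' @return An object of class `polynomial_profile` with elements
#'   `coefficients` (length `degree + 1`), `adj_r_squared`, `basis`
#'   (description), `fit` (the `lm`).
#' @export
fit_polynomial_profile <- function(converged, degree = 4) {
  stopifnot(inherits(converged, "converged_profile"))
  df <- tibble::tibble(depth_cm = converged$depth_cm,
                       ln_point = log(converged$point)) |>
    dplyr::filter(!is.na(.data$ln_point))
  if (nrow(df) < degree + 2) {
    stop("need more defined points (", nrow(df), ") than parameters (",
         degree + 1, ") to fit the polynomial profile", call. = FALSE)
  }
  fit <- lm(ln_point ~ poly(depth_cm, degree), data = df)
  structure(
    list(coefficients = setNames(unname(coef(fit)),
                                 c("c0", paste0("c", seq_len(degree)))),
         adj_r_squared = summary(fit)$adj.r.squared,
         degree = degree,
         basis = sprintf(
           "orthonormal polynomial basis (stats::poly) of degree %d on depth_cm; response ln(particle size, mm)",
           degree),
         property = attr(converged, "property"),
         fit = fit),
    class = "polynomial_profile"
  )
}

#' @export
print.polynomial_profile <- function(x, ...) {
  cat("Quartic profile model of ln(particle size) on orthogonalized depth\n")
  print(round(x$coefficients, 4))
  cat(sprintf("adj. R-squared = %.4f (n = %d)\n", x$adj_r_squared,
              length(x$fit$residuals)))
  invisible(x)
}

#' @export
predict.polynomial_profile <- function(object, depth_cm, ...) {
  ln <- predict(object$fit, newdata = data.frame(depth_cm = depth_cm))
  unname(exp(ln))
}

#' Fit the exponential carbon profile model
#'
#' Nonlinear least squares of the converged carbon points on
#' `C_o * exp(-k * depth)`: `C_o` is the carbon content at the soil surface
#' (g C/kg) and `k` the decay rate per cm (constrained non-negative). The
#' fit is seeded by the closed-form log-linear regression of `ln(point)` on
#' depth and refined with Levenberg-Marquardt least squares on the original
#' scale.
#'
#' @param converged A `converged_profile` of carbon, from
#'   [build_converged_profile()].
#' @return An object of class `exponential_profile` with elements
#'   `surface_value` (`C_o`, g/kg), `decay_rate` (`k`, per cm), `fit`.
#' @export
fit_exponential_profile <- function(converged) {
  stopifnot(inherits(converged, "converged_profile"))
  df <- tibble::tibble(depth_cm = converged$depth_cm,
                       point = converged$point) |>
    dplyr::filter(!is.na(.data$point))
  if (nrow(df) < 3) stop("need at least 3 defined points", call. = FALSE)
  if (any(df$point <= 0)) {
    stop("carbon points must be strictly positive", call. = FALSE)
  }
  seed <- lm(log(point) ~ depth_cm, data = df)
  start <- list(Co = exp(unname(coef(seed)[1])),
                k = max(0, -unname(coef(seed)[2])))
  seed_resid <- df$point - start$Co * exp(-start$k * df$depth_cm)
  if (sum(seed_resid^2) <= 1e-18 * sum(df$point^2)) {
    # log-linear seed already interpolates the points; nothing to refine
    est <- c(Co = start$Co, k = start$k)
    fit <- seed
  } else {
    fit <- minpack.lm::nlsLM(point ~ Co * exp(-k * depth_cm), data = df,
                             start = start,
                             lower = c(Co = .Machine$double.eps, k = 0))
    est <- coef(fit)
  }
  structure(
    list(surface_value = unname(est["Co"]), decay_rate = unname(est["k"]),
         property = attr(converged, "property"), fit = fit),
    class = "exponential_profile"
  )
}

#' @export
print.exponential_profile <- function(x, ...) {
  cat(sprintf(
    "Exponential carbon profile: C(x) = %.4g * exp(-%.6g * x)  [g C/kg, x in cm]\n",
    x$surface_value, x$decay_rate))
  invisible(x)
}

#' @export
predict.exponential_profile <- function(object, depth_cm, ...) {
  object$surface_value * exp(-object$decay_rate * depth_cm)
}

#' Urban-minus-reference differences at stated depths
#'
#' Extracts, for each pair, the difference `urban - reference` of the sliced
#' property at the requested depths. Depth `d` reads the slice containing it
#' (`floor(d)`); the bottom of the analysis window (150 cm) maps to the
#' deepest slice.
#'
#' @param sliced Sliced-profile tibble (one property) covering both members
#'   of every pair.
#' @param pairs Pairing tibble.
#' @param depths Depths in cm within `[0, 150]`; default `c(0, 50, 100, 150)`.
#' @return A tibble with one row per pair and depth: ids, `depth_cm`,
#'   `urban_value`, `reference_value`, `difference`.
#' @export
depth_differences <- function(sliced, pairs, depths = c(0, 50, 100, 150)) {
  stopifnot(all(c("pedon_id", "depth_cm", "value") %in% names(sliced)))
  max_slice <- max(sliced$depth_cm)
  if (any(depths < 0 | depths > max_slice + 1)) {
    stop("depths must lie within [0, ", max_slice + 1, "] cm", call. = FALSE)
  }
  slice_of <- pmin(floor(depths), max_slice)
  want <- tibble::tibble(depth_cm = depths, slice = slice_of)
  urb <- sliced |>
    dplyr::select(urban_pedon_id = "pedon_id", slice = "depth_cm",
                  urban_value = "value")
  ref <- sliced |>
    dplyr::select(reference_pedon_id = "pedon_id", slice = "depth_cm",
                  reference_value = "value")
  tibble::as_tibble(pairs) |>
    dplyr::select("urban_pedon_id", "reference_pedon_id") |>
    dplyr::cross_join(want) |>
    dplyr::left_join(urb, by = c("urban_pedon_id", "slice")) |>
    dplyr::left_join(ref, by = c("reference_pedon_id", "slice")) |>
    dplyr::mutate(difference = .data$urban_value - .data$reference_value) |>
    dplyr::select("urban_pedon_id", "reference_pedon_id", "depth_cm",
                  "urban_value", "reference_value", "difference")
}

#' Summarize depth differences
#'
#' @param diffs Output of [depth_differences()].
#' @return One row per depth: `n`, `mean_difference`, `min_difference`,
#'   `max_difference`.
#' @export
summarize_depth_differences <- function(diffs) {
  diffs |>
    dplyr::filter(!is.na(.data$difference)) |>
    dplyr::group_by(.data$depth_cm) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_difference = mean(.data$difference),
                     min_difference = min(.data$difference),
                     max_difference = max(.data$difference),
                     .groups = "drop")
}

#' Whole-profile IPA convergence regression
#'
#' Tests convergence of profile anisotropy itself: ordinary least squares of
#' the log urban:reference IPA ratio on the log reference IPA, one point per
#' pair. A negative slope means urbanization raised anisotropy where the
#' pre-urban profile was uniform and lowered it where it was strongly
#' structured; the converged IPA is `exp(-intercept/slope)`.
#'
#' @param ratios Output of [ipa_ratios()] for a single property (columns
#'   `reference_ipa`, `urban_ipa` or `ipa_ratio`).
#' @return An object of class `ipa_convergence`: `intercept`, `slope`,
#'   `f_statistic`, `df` (numerator, denominator), `p_value`, `n_pairs`,
#'   `converged_ipa` (NA unless slope < 0), `property`, `fit`.
#' @export
ipa_convergence_regression <- function(ratios) {
  stopifnot(all(c("reference_ipa", "urban_ipa") %in% names(ratios)))
  prop <- if ("property" %in% names(ratios) && nrow(ratios)) {
    pr <- unique(ratios$property)
    if (length(pr) != 1) {
      stop("ipa_convergence_regression expects a single property, got: ",
           paste(pr, collapse = ", "), call. = FALSE)
    }
    pr
  } else NA_character_
  df <- tibble::as_tibble(ratios) |>
    dplyr::filter(!is.na(.data$reference_ipa), !is.na(.data$urban_ipa))
  if (nrow(df) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(df$reference_ipa <= 0 | df$urban_ipa <= 0)) {
    stop("IPA values must be positive (apply the floor first)",
         call. = FALSE)
  }
  df <- dplyr::mutate(df, ln_ref = log(.data$reference_ipa),
                      ln_ratio = log(.data$urban_ipa) -
                        log(.data$reference_ipa))
  if (dplyr::n_distinct(df$ln_ref) < 2) {
    stop("degenerate design: all reference IPA values equal", call. = FALSE)
  }
  fit <- lm(ln_ratio ~ ln_ref, data = df)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  fstat <- unname(sm$fstatistic)
  structure(
    list(intercept = intercept, slope = slope,
         f_statistic = fstat[1], df = c(fstat[2], fstat[3]),
         p_value = sm$coefficients[2, 4],
         n_pairs = nrow(df),
         converged_ipa = if (!is.na(slope) && slope < 0) {
           convergence_point(intercept, slope)
         } else NA_real_,
         r_squared = sm$r.squared,
         property = prop, fit = fit, data = df),
    class = "ipa_convergence"
  )
}

#' @export
print.ipa_convergence <- function(x, ...) {
  cat("IPA convergence regression: ln(urban/reference IPA) ~ ln(reference IPA)\n")
  cat(sprintf("  property: %s, n = %d pairs\n", x$property, x$n_pairs))
  cat(sprintf("  intercept = %.3f, slope = %.3f, F(%d,%d) = %.1f, p = %.3g\n",
              x$intercept, x$slope, x$df[1], x$df[2], x$f_statistic,
              x$p_value))
  if (!is.na(x$converged_ipa)) {
    cat(sprintf("  converged IPA = %.1f\n", x$converged_ipa))
  } else {
    cat("  no convergence point (slope not negative)\n")
  }
  invisible(x)
}

#' Tidiers for pedoconverge model objects
#'
#' Broom-style one-row-per-term summaries.
#'
#' @param x A fitted pedoconverge model object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-pedoconverge
NULL

#' Model-level summaries for pedoconverge model objects
#'
#' Broom-style one-row model summaries.
#'
#' @param x A fitted pedoconverge model object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @name glance-pedoconverge
NULL

#' @rdname tidy-pedoconverge
#' @method tidy ipa_convergence
#' @export
tidy.ipa_convergence <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = c("(Intercept)", "ln_reference_ipa"),
                 estimate = c(x$intercept, x$slope),
                 std.error = sm[, 2], statistic = sm[, 3],
                 p.value = sm[, 4])
}

#' @rdname glance-pedoconverge
#' @method glance ipa_convergence
#' @export
glance.ipa_convergence <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, statistic = x$f_statistic,
                 df = x$df[1], df.residual = x$df[2], p.value = x$p_value,
                 nobs = x$n_pairs, converged_ipa = x$converged_ipa)
}

#' @rdname tidy-pedoconverge
#' @method tidy polynomial_profile
#' @export
tidy.polynomial_profile <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname glance-pedoconverge
#' @method glance polynomial_profile
#' @export
glance.polynomial_profile <- function(x, ...) {
  tibble::tibble(adj.r.squared = x$adj_r_squared,
                 nobs = length(x$fit$residuals))
}

#' @rdname tidy-pedoconverge
#' @method tidy exponential_profile
#' @export
tidy.exponential_profile <- function(x, ...) {
  tibble::tibble(term = c("surface_value", "decay_rate"),
                 estimate = c(x$surface_value, x$decay_rate))
}

#' @rdname glance-pedoconverge
#' @method glance exponential_profile
#' @export
glance.exponential_profile <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(sigma = sm$sigma, nobs = length(stats::residuals(x$fit)))
}
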