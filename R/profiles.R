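# Horizon-table contract used throughout the package: one row per described
# horizon, columns
#   pedon_id, condition ("urban"/"reference"), city, land_use,
#   top_cm, bottom_cm, texture_class, munsell_value, carbon_g_kg
# city/land_use optional; texture_class/munsell_value/carbon_g_kg may be NA
# but at least one must be present per horizon.

.horizon_required_cols <- c("pedon_id", "condition", "top_cm", "bottom_cm")

check_horizon_cols <- function(horizons, call = sys.call(-1)) {
  missing_cols <- setdiff(.horizon_required_cols, names(horizons))
  if (length(missing_cols)) {
    stop("horizon table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("city", "land_use")) {
    if (!col %in% names(horizons)) horizons[[col]] <- NA_character_
  }
  for (col in c("texture_class", "munsell_value", "carbon_g_kg")) {
    if (!col %in% names(horizons)) horizons[[col]] <- NA
  }
  tibble::as_tibble(horizons)
}

#' Validate horizon-structured pedon profiles
#'
#' Checks every pedon in a horizon table against the profile invariants:
#' depths satisfy `0 <= top < bottom`, the first horizon starts at the ground
#' surface, horizons are contiguous (each bottom equals the next top) and
#' non-overlapping, and every horizon carries at least one of texture class,
#' Munsell value, or measured carbon. A validator, not a gatekeeper: it
#' reports violations and never throws.
#'
#' @param horizons Horizon table (see package conventions): one row per
#'   horizon with at least `pedon_id`, `condition`, `top_cm`, `bottom_cm`.
#' @return A tibble of violations with columns `pedon_id`, `horizon`
#'   (1-based index within the pedon, ordered by top depth), `rule`, and
#'   `detail`; zero rows when every profile is well formed.
#' @export
#' @examples
#' h <- tibble::tibble(pedon_id = "P1", condition = "reference",
#'                     top_cm = c(0, 30), bottom_cm = c(30, 150),
#'                     texture_class = "loam", munsell_value = 4,
#'                     carbon_g_kg = NA_real_)
#' validate_profiles(h)
validate_profiles <- function(horizons) {
  horizons <- check_horizon_cols(horizons)
  one <- function(df) {
    ord <- order(df$top_cm)
    df <- df[ord, ]
    n <- nrow(df)
    v <- list()
    add <- function(i, rule, detail) {
      v[[length(v) + 1]] <<- tibble::tibble(horizon = i, rule = rule,
                                            detail = detail)
    }
    bad_depth <- !(df$top_cm >= 0 & df$top_cm < df$bottom_cm)
    for (i in which(bad_depth)) {
      add(i, "bad depths",
          sprintf("requires 0 <= top (%g) < bottom (%g)",
                  df$top_cm[i], df$bottom_cm[i]))
    }
    if (n > 0 && !is.na(df$top_cm[1]) && df$top_cm[1] != 0) {
      add(1L, "does not start at surface",
          sprintf("first horizon starts at %g cm", df$top_cm[1]))
    }
    if (n > 1) {
      gap <- df$top_cm[-1] - df$bottom_cm[-n]
      for (i in which(abs(gap) > 1e-9)) {
        add(i + 1L,
            if (gap[i] > 0) "non-contiguous" else "overlapping",
            sprintf("horizon %d ends at %g cm but horizon %d starts at %g cm",
                    i, df$bottom_cm[i], i + 1L, df$top_cm[i + 1]))
      }
    }
    no_prop <- is.na(df$texture_class) & is.na(df$munsell_value) &
      is.na(df$carbon_g_kg)
    for (i in which(no_prop)) {
      add(i, "no property",
          "horizon has none of texture_class, munsell_value, carbon_g_kg")
    }
    if (!length(v)) {
      return(tibble::tibble(horizon = integer(), rule = character(),
                            detail = character()))
    }
    dplyr::bind_rows(v)
  }
  horizons |>
    dplyr::group_by(.data$pedon_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

# Per-horizon property values for one pedon's sorted horizon rows.
horizon_values <- function(df, property, model, midpoints, predict_all,
                           max_depth) {
  need <- df$top_cm < max_depth
  vals <- rep(NA_real_, nrow(df))
  if (property == "particle_size_mm") {
    miss <- need & is.na(df$texture_class)
    if (any(miss)) {
      i <- which(miss)[1]
      stop(sprintf(
        "pedon %s: horizon %d (%g-%g cm) has no texture_class; cannot derive particle size",
        df$pedon_id[1], i, df$top_cm[i], df$bottom_cm[i]), call. = FALSE)
    }
    vals[need] <- class_particle_size(df$texture_class[need], midpoints)
  } else if (property == "carbon_g_per_kg") {
    use_meas <- need & !predict_all & !is.na(df$carbon_g_kg)
    vals[use_meas] <- df$carbon_g_kg[use_meas]
    use_pred <- need & !use_meas
    miss <- use_pred & is.na(df$munsell_value)
    # fall back to measurement when predict_all requested but color missing
    fallback <- miss & !is.na(df$carbon_g_kg)
    vals[fallback] <- df$carbon_g_kg[fallback]
    use_pred[fallback] <- FALSE
    miss <- miss & !fallback
    if (any(miss)) {
      i <- which(miss)[1]
      stop(sprintf(
        paste0("pedon %s: horizon %d (%g-%g cm) has neither munsell_value nor ",
               "carbon_g_kg; supply a measurement or drop the horizon"),
        df$pedon_id[1], i, df$top_cm[i], df$bottom_cm[i]), call. = FALSE)
    }
    if (any(use_pred)) {
      vals[use_pred] <- predict_carbon(df$munsell_value[use_pred], model)
    }
  } else {
    stop("unknown property: ", property, call. = FALSE)
  }
  vals
}

#' Resolve horizon profiles to 1-cm depth slices
#'
#' Converts each pedon's horizon records into a per-centimeter step-function
#' profile of one property over `[0, max_depth)` cm. Slice `i` covers the
#' depth interval `[i, i+1)` and takes exactly the value of the horizon
#' containing the slice midpoint `i + 0.5` (no interpolation; horizon
#' boundaries at non-integer depths are resolved by midpoint containment).
#' Slices below the deepest described horizon are `NA`, never zero-filled.
#'
#' Particle size (`"particle_size_mm"`) is derived from the USDA texture
#' class via [centroid_of_class()] and [geometric_mean_diameter()]; carbon
#' (`"carbon_g_per_kg"`) uses the measured value where present and otherwise
#' predicts from the Munsell value via [predict_carbon()] (set
#' `predict_all = TRUE` to predict for every horizon regardless of
#' measurements).
#'
#' @param horizons Horizon table.
#' @param property `"particle_size_mm"` or `"carbon_g_per_kg"`.
#' @param max_depth Truncation depth in cm (default 150).
#' @param model A [color_carbon_model()] used for carbon prediction.
#' @param midpoints Separate diameters for particle size, see
#'   [separate_midpoints()].
#' @param predict_all Logical; predict carbon from color even where a
#'   measurement exists.
#' @return A tibble with one row per pedon and slice: `pedon_id`, `property`,
#'   `depth_cm` (integer 0 to `max_depth - 1`, the top of the slice),
#'   `value`, and `depth_available` (cm of profile actually described,
#'   capped at `max_depth`).
#' @export
#' @examples
#' h <- tibble::tibble(pedon_id = "P1", condition = "reference",
#'                     top_cm = c(0, 50), bottom_cm = c(50, 150),
#'                     texture_class = c("loam", "clay loam"),
#'                     munsell_value = c(3, 5), carbon_g_kg = NA_real_)
#' slice_profiles(h, "particle_size_mm")
slice_profiles <- function(horizons,
                           property = c("particle_size_mm", "carbon_g_per_kg"),
                           max_depth = 150,
                           model = color_carbon_model(),
                           midpoints = separate_midpoints(),
                           predict_all = FALSE) {
  property <- match.arg(property)
  horizons <- check_horizon_cols(horizons)
  stopifnot(max_depth >= 1)
  viol <- validate_profiles(horizons)
  if (nrow(viol)) {
    stop("invalid profiles; first violation: pedon ", viol$pedon_id[1],
         ", horizon ", viol$horizon[1], ": ", viol$rule[1], " (",
         viol$detail[1], ")", call. = FALSE)
  }
  mids <- seq_len(max_depth) - 0.5
  one <- function(df) {
    df <- df[order(df$top_cm), ]
    vals <- horizon_values(df, property, model, midpoints, predict_all,
                           max_depth)
    idx <- findInterval(mids, df$top_cm)
    bottom <- max(df$bottom_cm)
    slice_vals <- ifelse(idx >= 1 & mids < bottom, vals[pmax(idx, 1)],
                         NA_real_)
    tibble::tibble(
      property = property,
      depth_cm = 0:(max_depth - 1),
      value = slice_vals,
      depth_available = min(max_depth, bottom)
    )
  }
  horizons |>
    dplyr::group_by(.data$pedon_id) |>
    dplyr::group_modify(~ one(dplyr::mutate(.x, pedon_id = .y$pedon_id))) |>
    dplyr::ungroup()
}

#' Pair urban pedons with their pre-urban reference series
#'
#' Validates a pairing table against a horizon table: every
#' `urban_pedon_id` must resolve to a pedon with `condition == "urban"` and
#' every `reference_pedon_id` to one with `condition == "reference"`. Many
#' urban pedons may share one reference series.
#'
#' @param horizons Horizon table containing both urban and reference pedons.
#' @param mapping A data frame with columns `urban_pedon_id`,
#'   `reference_pedon_id`.
#' @return The validated pairing tibble (one row per urban pedon).
#' @export
pair_profiles <- function(horizons, mapping) {
  horizons <- check_horizon_cols(horizons)
  stopifnot(all(c("urban_pedon_id", "reference_pedon_id") %in% names(mapping)))
  mapping <- tibble::as_tibble(mapping)
  if (nrow(mapping) == 0) return(mapping)
  cond <- horizons |>
    dplyr::distinct(.data$pedon_id, .data$condition)
  urb <- cond$pedon_id[cond$condition == "urban"]
  ref <- cond$pedon_id[cond$condition == "reference"]
  bad_u <- !(mapping$urban_pedon_id %in% urb)
  bad_r <- !(mapping$reference_pedon_id %in% ref)
  if (any(bad_u | bad_r)) {
    msgs <- c(
      if (any(bad_u)) paste0("unmatched urban ids: ",
        paste(unique(mapping$urban_pedon_id[bad_u]), collapse = ", ")),
      if (any(bad_r)) paste0("unmatched reference ids: ",
        paste(unique(mapping$reference_pedon_id[bad_r]), collapse = ", "))
    )
    stop("pairing table references unknown pedons (rows ",
         paste(which(bad_u | bad_r), collapse = ", "), "); ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }
  if (anyDuplicated(mapping$urban_pedon_id)) {
    stop("pairing table lists an urban pedon more than once: ",
         paste(unique(mapping$urban_pedon_id[duplicated(mapping$urban_pedon_id)]),
               collapse = ", "), call. = FALSE)
  }
  mapping
}
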