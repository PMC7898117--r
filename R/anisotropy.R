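#' Index of Profile Anisotropy
#'
#' The IPA of a sliced profile is the sum over 1-cm slices of the absolute
#' deviation of the slice value from the whole-profile mean, scaled by that
#' mean: `IPA = sum(|x_i - mean(x)|) / mean(x)`. It is unitless,
#' non-negative, scale invariant, and exactly 0 for an entirely uniform
#' profile. Missing slices (profiles described to less than the full depth)
#' are excluded from both the sum and the mean; `n_slices_used` reports how
#' many slices contributed so downstream filters can require full coverage.
#'
#' @param sliced A sliced-profile tibble from [slice_profiles()] (may hold
#'   many pedons and both properties).
#' @return A tibble with one row per pedon and property: `pedon_id`,
#'   `property`, `raw_ipa`, `n_slices_used`, `profile_mean`.
#' @export
#' @examples
#' h <- tibble::tibble(pedon_id = "P1", condition = "reference",
#'                     top_cm = c(0, 75), bottom_cm = c(75, 150),
#'                     texture_class = NA, munsell_value = NA,
#'                     carbon_g_kg = c(10, 20))
#' compute_ipa(slice_profiles(h, "carbon_g_per_kg"))
compute_ipa <- function(sliced) {
  stopifnot(all(c("pedon_id", "property", "depth_cm", "value") %in%
                  names(sliced)))
  one <- function(df) {
    x <- df$value[!is.na(df$value)]
    if (!length(x)) {
      stop("pedon ", df$pedon_id[1], " (", df$property[1],
           "): all slices missing; cannot compute IPA", call. = FALSE)
    }
    mu <- mean(x)
    if (mu == 0) {
      stop("pedon ", df$pedon_id[1], " (", df$property[1],
           "): profile mean is zero; IPA undefined", call. = FALSE)
    }
    tibble::tibble(raw_ipa = sum(abs(x - mu)) / mu,
                   n_slices_used = length(x),
                   profile_mean = mu)
  }
  sliced |>
    dplyr::group_by(.data$pedon_id, .data$property) |>
    dplyr::group_modify(~ one(dplyr::mutate(.x, pedon_id = .y$pedon_id,
                                            property = .y$property))) |>
    dplyr::ungroup()
}

#' Minimum-IPA floors per property
#'
#' Profiles whose class- and color-derived values are constant yield a raw
#' IPA of exactly 0 — a limit of the field methods' resolution rather than
#' evidence of a truly uniform profile, and a singularity in the
#' urban:reference IPA ratio. Zeroes are therefore replaced by a per-property
#' minimum IPA. Defaults are the packaged constants 13.6 (particle size) and
#' 10.7 (carbon), one quarter of the median reference-profile IPA; see
#' [reference_floor_from_data()] to derive floors from your own reference
#' set.
#'
#' @param particle_size_floor,carbon_floor Positive floor values.
#' @return Named list of floors keyed by property name.
#' @export
ipa_floors <- function(particle_size_floor = 13.6, carbon_floor = 10.7) {
  stopifnot(particle_size_floor > 0, carbon_floor > 0)
  list(particle_size_mm = particle_size_floor,
       carbon_g_per_kg = carbon_floor)
}

#' Apply the minimum-IPA floor
#'
#' Adds `floored_ipa` and `floor_applied` to an IPA table: rows with
#' `raw_ipa == 0` take the configured floor for their property, all others
#' pass through unchanged.
#'
#' @param ipa IPA tibble from [compute_ipa()].
#' @param floors Named list of per-property floors, see [ipa_floors()].
#' @return The input tibble with `floored_ipa` and `floor_applied` columns.
#' @export
apply_ipa_floor <- function(ipa, floors = ipa_floors()) {
  stopifnot(all(c("property", "raw_ipa") %in% names(ipa)))
  missing_floor <- setdiff(unique(ipa$property), names(floors))
  if (length(missing_floor)) {
    stop("no floor configured for property: ",
         paste(missing_floor, collapse = ", "), call. = FALSE)
  }
  fl <- unlist(floors)[ipa$property]
  ipa |>
    dplyr::mutate(
      floor_applied = .data$raw_ipa == 0,
      floored_ipa = ifelse(.data$floor_applied, unname(fl), .data$raw_ipa)
    )
}

#' Derive a minimum-IPA floor from reference profiles
#'
#' The default rule takes one quarter of the median of the positive
#' reference IPA values ("quarter_median"); the 25th percentile of the
#' positive values is available as `method = "lower_quartile"`.
#'
#' @param reference_ipas Numeric vector of raw reference IPA values (at least
#'   3 positive values required).
#' @param method `"quarter_median"` (default) or `"lower_quartile"`.
#' @return A single positive floor value.
#' @export
#' @examples
#' reference_floor_from_data(c(40, 54.4, 60))
reference_floor_from_data <- function(reference_ipas,
                                      method = c("quarter_median",
                                                 "lower_quartile")) {
  method <- match.arg(method)
  x <- reference_ipas[!is.na(reference_ipas) & reference_ipas > 0]
  if (length(x) < 3) {
    stop("need at least 3 positive reference IPA values, got ", length(x),
         call. = FALSE)
  }
  switch(method,
         quarter_median = 0.25 * median(x),
         lower_quartile = unname(quantile(x, 0.25)))
}

#' Urban:reference IPA ratios for paired pedons
#'
#' Joins floored urban and reference IPA values over a pairing table and
#' forms the ratio `urban IPA / reference IPA` per property. Ratios greater
#' than 1 mean urbanization increased profile anisotropy, 1 means no change,
#' less than 1 a more uniform urban profile.
#'
#' @param ipa Floored IPA tibble from [apply_ipa_floor()] covering both
#'   members of every pair.
#' @param pairs Pairing tibble (`urban_pedon_id`, `reference_pedon_id`).
#' @return A tibble with one row per pair and property: the pair ids,
#'   `property`, `urban_ipa`, `reference_ipa`, `ipa_ratio`.
#' @export
ipa_ratios <- function(ipa, pairs) {
  stopifnot(all(c("pedon_id", "property", "floored_ipa") %in% names(ipa)),
            all(c("urban_pedon_id", "reference_pedon_id") %in% names(pairs)))
  urb <- ipa |>
    dplyr::select(urban_pedon_id = "pedon_id", "property",
                  urban_ipa = "floored_ipa")
  ref <- ipa |>
    dplyr::select(reference_pedon_id = "pedon_id", "property",
                  reference_ipa = "floored_ipa")
  out <- tibble::as_tibble(pairs) |>
    dplyr::inner_join(urb, by = "urban_pedon_id",
                      relationship = "many-to-many") |>
    dplyr::inner_join(ref, by = c("reference_pedon_id", "property"))
  if (any(out$urban_ipa <= 0 | out$reference_ipa <= 0)) {
    stop("non-positive floored IPA encountered; apply_ipa_floor() first",
         call. = FALSE)
  }
  dplyr::mutate(out, ipa_ratio = .data$urban_ipa / .data$reference_ipa)
}
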