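# Synthetic paired-pedon generator. References carry the classic anisotropic
# depth functions (clay bulge at intermediate depth, exponentially declining
# carbon); urbanization pulls each property toward a depth-dependent target
# on the log scale with strength b: ln(urban) = (1-b) ln c*(x) + b ln(ref).
# Values are round-tripped through texture classes and integer Munsell chips
# so the synthetic path suffers the same quantization as field data.

#' Configuration for the synthetic paired-pedon generator
#'
#' Defaults emulate the study conditions the package targets: 332 paired
#' cores spread over 11 cities; reference carbon declining exponentially from
#' a lognormal surface level (median 20 g/kg, sdlog 0.4; decay
#' 0.0059 +/- 0.0015 per cm); a three-zone texture profile whose middle zone
#' (clay bulge, window inside 30-80 cm) is drawn from finer classes than the
#' surface and deep zones; urbanization pulling with strength `pull_strength`
#' toward a fine, low-carbon fill target (`c*`): carbon
#' `18.4 * exp(-0.005868 x)` g/kg and particle size log-linear from 0.08 mm
#' at the surface to 0.04 mm at 150 cm. Lognormal noise with standard
#' deviation `noise_sd` (log scale) enters both the reference carbon curve
#' and the urbanization pull.
#'
#' @param n_pairs Number of urban/reference pairs.
#' @param seed Master seed; per-pedon substreams are derived from it so a
#'   dataset is reproducible under partial regeneration.
#' @param pull_strength Pull strength `b` in `[0, 1]`: 1 leaves the reference
#'   untouched, 0 replaces it with the target.
#' @param noise_sd Lognormal noise scale (natural-log units).
#' @param n_cities Number of city labels to spread pairs over.
#' @param reference_thickness_cm,urban_thickness_cm Mean horizon thicknesses.
#' @param carbon_surface_meanlog,carbon_surface_sdlog Lognormal parameters of
#'   the reference surface carbon (g/kg).
#' @param carbon_decay_mean,carbon_decay_sd Per-pedon decay rate (per cm).
#' @param surface_classes,bulge_classes,deep_classes USDA class pools per
#'   depth zone.
#' @param bulge_window Two-element range (cm) from which each pedon's clay
#'   bulge top is drawn; the bulge bottom is drawn from
#'   `bulge_window + 30` cm.
#' @param carbon_cstar_surface,carbon_cstar_decay Convergence target for
#'   carbon: `c*(x) = surface * exp(-decay * x)`.
#' @param particle_cstar_surface,particle_cstar_deep Convergence target for
#'   particle size, log-linear between these endpoints over 0-150 cm.
#' @param munsell_range Integer Munsell value chips available for encoding.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pairs = 332, seed = 1,
                             pull_strength = 0.5, noise_sd = 0.1,
                             n_cities = 11,
                             reference_thickness_cm = 25,
                             urban_thickness_cm = 15,
                             carbon_surface_meanlog = log(20),
                             carbon_surface_sdlog = 0.4,
                             carbon_decay_mean = 0.0059,
                             carbon_decay_sd = 0.0015,
                             surface_classes = c("loamy sand", "sandy loam",
                                                 "loam", "silt loam"),
                             bulge_classes = c("sandy clay loam", "clay loam",
                                               "silty clay loam", "silty clay",
                                               "clay"),
                             deep_classes = c("sand", "loamy sand",
                                              "sandy loam", "loam"),
                             bulge_window = c(30, 50),
                             carbon_cstar_surface = 18.4,
                             carbon_cstar_decay = 0.005868,
                             particle_cstar_surface = 0.08,
                             particle_cstar_deep = 0.04,
                             munsell_range = c(2L, 8L)) {
  stopifnot(n_pairs >= 1, pull_strength >= 0, pull_strength <= 1,
            noise_sd >= 0, carbon_cstar_surface > 0,
            particle_cstar_surface > 0, particle_cstar_deep > 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# Convergence target c*(depth), property units.
synthetic_cstar <- function(config, property, depth_cm) {
  switch(property,
    carbon_g_per_kg = config$carbon_cstar_surface *
      exp(-config$carbon_cstar_decay * depth_cm),
    particle_size_mm = exp(log(config$particle_cstar_surface) +
      (depth_cm / 150) * (log(config$particle_cstar_deep) -
                            log(config$particle_cstar_surface))),
    stop("unknown property: ", property)
  )
}

# Invert the pedotransfer to the nearest integer Munsell chip.
encode_munsell <- function(carbon_g_kg, config,
                           model = color_carbon_model()) {
  v <- (log(carbon_g_kg) - model$intercept) / model$slope
  pmin(pmax(round(v), config$munsell_range[1]), config$munsell_range[2])
}

# Nearest USDA class to a continuous geometric mean diameter, log scale.
encode_texture_class <- function(particle_size_mm) {
  tab <- usda_texture_centroids()
  gmd <- geometric_mean_diameter(tab)
  tab$texture_class[vapply(particle_size_mm, function(p) {
    which.min(abs(log(gmd) - log(p)))
  }, integer(1))]
}

# Horizon breakpoints: lognormal thicknesses, 5 cm minimum, truncated at
# max_depth.
draw_breaks <- function(mean_thickness, max_depth = 150) {
  tops <- 0
  while (tops[length(tops)] < max_depth) {
    thick <- max(5, rlnorm(1, meanlog = log(mean_thickness), sdlog = 0.35))
    tops <- c(tops, min(max_depth, tops[length(tops)] + thick))
  }
  tops
}

draw_pedon_params <- function(config) {
  bulge_top <- runif(1, config$bulge_window[1], config$bulge_window[2])
  list(
    surface_class = sample(config$surface_classes, 1),
    bulge_class = sample(config$bulge_classes, 1),
    deep_class = sample(config$deep_classes, 1),
    bulge_top = bulge_top,
    bulge_bottom = runif(1, config$bulge_window[1] + 30,
                         config$bulge_window[2] + 30),
    carbon_surface = rlnorm(1, config$carbon_surface_meanlog,
                            config$carbon_surface_sdlog),
    carbon_decay = max(0.001, rnorm(1, config$carbon_decay_mean,
                                    config$carbon_decay_sd))
  )
}

#' Generate one synthetic pre-urban reference profile
#'
#' Draws horizon breakpoints and per-pedon parameters (texture classes per
#' depth zone, surface carbon, decay rate), evaluates the generating depth
#' functions at each horizon midpoint, and encodes them back to a USDA
#' texture class and an integer Munsell value — so downstream analysis
#' exercises the same decoding path as field data. Uses the current RNG
#' state; see [generate_dataset()] for the seeded wrapper.
#'
#' @param config A [synthetic_config()].
#' @param pedon_id,city Identifiers for the emitted rows.
#' @param params Per-pedon generating parameters; drawn if `NULL`.
#' @return A horizon tibble (condition `"reference"`) with the generating
#'   parameters attached as attribute `"params"`.
#' @export
generate_reference_profile <- function(config, pedon_id = "R001",
                                       city = "city_01", params = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(params)) params <- draw_pedon_params(config)
  tops <- draw_breaks(config$reference_thickness_cm)
  n <- length(tops) - 1
  mid <- (tops[-length(tops)] + tops[-1]) / 2
  zone_class <- ifelse(mid < params$bulge_top, params$surface_class,
                       ifelse(mid < params$bulge_bottom, params$bulge_class,
                              params$deep_class))
  carbon <- params$carbon_surface * exp(-params$carbon_decay * mid) *
    exp(rnorm(n, 0, config$noise_sd))
  out <- tibble::tibble(
    pedon_id = pedon_id, condition = "reference", city = city,
    land_use = NA_character_,
    top_cm = tops[-length(tops)], bottom_cm = tops[-1],
    texture_class = zone_class,
    munsell_value = as.numeric(encode_munsell(carbon, config)),
    carbon_g_kg = NA_real_
  )
  attr(out, "params") <- params
  out
}

# Value of a horizon table's decoded property at given depths (one pedon).
decoded_value_at <- function(horizons, depth_cm, property) {
  h <- horizons[order(horizons$top_cm), ]
  idx <- pmax(findInterval(depth_cm, h$top_cm), 1)
  if (property == "particle_size_mm") {
    class_particle_size(h$texture_class[idx])
  } else {
    predict_carbon(h$munsell_value[idx])
  }
}

#' Urbanize a reference profile
#'
#' Applies the multiplicative pull model per depth:
#' `ln(urban) = (1 - b) * ln(c*(depth)) + b * ln(reference) + noise`, where
#' the reference value is the profile's decoded (class/color) value. Urban
#' horizon boundaries refine the reference boundaries — reference breaks are
#' kept and spans thicker than the configured urban thickness are subdivided
#' — so with `b = 1` and zero noise the urbanized profile reproduces the
#' reference exactly, slice for slice. Pulled values are re-encoded to
#' texture classes and Munsell chips. Uses the current RNG state.
#'
#' @param reference A reference horizon tibble (one pedon), e.g. from
#'   [generate_reference_profile()].
#' @param config A [synthetic_config()].
#' @param pedon_id Identifier for the urban pedon; default prefixes the
#'   reference id with "U".
#' @return A horizon tibble with `condition = "urban"`.
#' @export
urbanize_profile <- function(reference, config,
                             pedon_id = paste0("U", sub("^R", "",
                                                        reference$pedon_id[1]))) {
  stopifnot(inherits(config, "synthetic_config"))
  ref <- reference[order(reference$top_cm), ]
  b <- config$pull_strength
  tops <- unlist(lapply(seq_len(nrow(ref)), function(i) {
    span <- ref$bottom_cm[i] - ref$top_cm[i]
    k <- max(1, ceiling(span / config$urban_thickness_cm))
    ref$top_cm[i] + span * (seq_len(k) - 1) / k
  }))
  bottoms <- c(tops[-1], max(ref$bottom_cm))
  mid <- (tops + bottoms) / 2
  n <- length(mid)

  r_ps <- decoded_value_at(ref, mid, "particle_size_mm")
  ln_u_ps <- (1 - b) * log(synthetic_cstar(config, "particle_size_mm", mid)) +
    b * log(r_ps) + rnorm(n, 0, config$noise_sd)

  r_c <- decoded_value_at(ref, mid, "carbon_g_per_kg")
  ln_u_c <- (1 - b) * log(synthetic_cstar(config, "carbon_g_per_kg", mid)) +
    b * log(r_c) + rnorm(n, 0, config$noise_sd)

  tibble::tibble(
    pedon_id = pedon_id, condition = "urban", city = ref$city[1],
    land_use = NA_character_,
    top_cm = tops, bottom_cm = bottoms,
    texture_class = encode_texture_class(exp(ln_u_ps)),
    munsell_value = as.numeric(encode_munsell(exp(ln_u_c), config)),
    carbon_g_kg = NA_real_
  )
}

#' Generate a full synthetic paired dataset with ground truth
#'
#' Produces `n_pairs` reference profiles, their urbanized counterparts, the
#' pairing table, and a truth object recording the generating convergence
#' targets: per depth and property, `c*`, the pull strength `b`, and the
#' implied per-slice regression coefficients `intercept = (1 - b) * ln(c*)`
#' and `slope = b - 1`. Fully reproducible from `config$seed`; each pair
#' draws from its own deterministic substream.
#'
#' @param config A [synthetic_config()].
#' @return A list: `horizons` (all pedons), `pairs`, `truth` (list with
#'   `slice_truth` tibble and `pedon_params` tibble).
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_config(n_pairs = 3, seed = 42))
#' dplyr::count(ds$horizons, condition)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_pairs
  pair_seeds <- (config$seed + 7919 * seq_len(n)) %% 2147483647
  cities <- sprintf("city_%02d", rep_len(seq_len(config$n_cities), n))
  pieces <- lapply(seq_len(n), function(i) {
    withr::with_seed(pair_seeds[i], {
      ref <- generate_reference_profile(config, sprintf("R%04d", i),
                                        cities[i])
      urb <- urbanize_profile(ref, config, sprintf("U%04d", i))
      list(ref = ref, urb = urb,
           params = tibble::as_tibble(attr(ref, "params")) |>
             dplyr::mutate(pedon_id = sprintf("R%04d", i), .before = 1))
    })
  })
  refs <- lapply(pieces, function(p) {
    r <- p$ref
    attr(r, "params") <- NULL
    r
  })
  horizons <- dplyr::bind_rows(refs, lapply(pieces, `[[`, "urb"))
  pairs <- tibble::tibble(urban_pedon_id = sprintf("U%04d", seq_len(n)),
                          reference_pedon_id = sprintf("R%04d", seq_len(n)))
  b <- config$pull_strength
  slice_truth <- tidyr::expand_grid(
    property = c("particle_size_mm", "carbon_g_per_kg"),
    depth_cm = 0:149
  ) |>
    dplyr::mutate(
      c_star = purrr::map2_dbl(.data$property, .data$depth_cm,
                               ~ synthetic_cstar(config, .x, .y + 0.5)),
      b = b,
      intercept = (1 - b) * log(.data$c_star),
      slope = b - 1
    )
  list(horizons = horizons, pairs = pairs,
       truth = list(slice_truth = slice_truth,
                    pedon_params = dplyr::bind_rows(
                      lapply(pieces, `[[`, "params")),
                    config = config))
}
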