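# CSV dialects: horizon table
#   pedon_id, condition, city, land_use, top_cm, bottom_cm, texture_class,
#   munsell_value, carbon_g_kg
# pairing table
#   urban_pedon_id, reference_pedon_id
# UTF-8, '.' decimal separator, empty field = missing.

.horizon_col_types <- function() {
  readr::cols(
    pedon_id = readr::col_character(),
    condition = readr::col_character(),
    city = readr::col_character(),
    land_use = readr::col_character(),
    top_cm = readr::col_double(),
    bottom_cm = readr::col_double(),
    texture_class = readr::col_character(),
    munsell_value = readr::col_double(),
    carbon_g_kg = readr::col_double()
  )
}

#' Read a horizon table
#'
#' Reads the package's CSV horizon dialect, checks the header, rejects
#' duplicate `(pedon_id, top_cm)` rows, and validates every profile with
#' [validate_profiles()] (violations are an error naming the pedon and rule).
#'
#' @param path CSV file path.
#' @param validate Logical; run profile validation (default `TRUE`).
#' @return A horizon tibble.
#' @export
read_horizon_table <- function(path, validate = TRUE) {
  stopifnot(file.exists(path))
  hdr <- names(readr::read_csv(path, n_max = 0,
                               col_types = readr::cols(.default = "c")))
  missing_cols <- setdiff(.horizon_required_cols, hdr)
  if (length(missing_cols)) {
    stop(path, ": header lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  spec <- .horizon_col_types()
  spec$cols <- spec$cols[intersect(names(spec$cols), hdr)]
  hz <- readr::read_csv(path, col_types = spec)
  if (nrow(hz) == 0) {
    warning(path, ": no horizon rows")
    return(check_horizon_cols(hz))
  }
  dup <- duplicated(hz[, c("pedon_id", "top_cm")])
  if (any(dup)) {
    stop(path, ": duplicate (pedon_id, top_cm) at data row(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  if (validate) {
    viol <- validate_profiles(hz)
    if (nrow(viol)) {
      stop(path, ": ", nrow(viol), " profile violation(s); first: pedon ",
           viol$pedon_id[1], ", horizon ", viol$horizon[1], ": ",
           viol$rule[1], " (", viol$detail[1], ")", call. = FALSE)
    }
  }
  check_horizon_cols(hz)
}

#' @rdname read_horizon_table
#' @param horizons Horizon tibble to write.
#' @export
write_horizon_table <- function(horizons, path) {
  horizons <- check_horizon_cols(horizons)
  cols <- c("pedon_id", "condition", "city", "land_use", "top_cm",
            "bottom_cm", "texture_class", "munsell_value", "carbon_g_kg")
  readr::write_csv(horizons[, cols], path, na = "")
  invisible(path)
}

#' Read a pairing table
#'
#' @param path CSV with columns `urban_pedon_id`, `reference_pedon_id`.
#' @return A tibble.
#' @export
read_pairing_table <- function(path) {
  stopifnot(file.exists(path))
  p <- readr::read_csv(path, col_types = readr::cols(
    urban_pedon_id = readr::col_character(),
    reference_pedon_id = readr::col_character()))
  need <- c("urban_pedon_id", "reference_pedon_id")
  if (!all(need %in% names(p))) {
    stop(path, ": header must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  p
}

#' Run the full convergence pipeline
#'
#' Ties the stages together the way the analysis is meant to be run: horizon
#' data (given, or simulated from `synthetic`) -> validation -> 1-cm slicing
#' per property -> IPA with floors and urban:reference ratios -> per-depth
#' convergence regressions -> converged profiles and their fitted models
#' (quartic for particle size, exponential for carbon) -> whole-profile IPA
#' convergence regression -> urban-minus-reference differences at the stated
#' depths. Deterministic given inputs and seed.
#'
#' @param horizons Horizon tibble covering urban and reference pedons, or
#'   `NULL` to simulate from `synthetic`.
#' @param pairs Pairing tibble; required when `horizons` is given.
#' @param synthetic A [synthetic_config()] used when `horizons` is `NULL`.
#' @param properties Properties to analyze.
#' @param floors Minimum-IPA configuration, see [ipa_floors()].
#' @param model Pedotransfer model for carbon prediction.
#' @param predict_all Predict carbon from color even where measured.
#' @param direction Regression direction, see [fit_slice_regressions()].
#' @param depths Depths (cm) for [depth_differences()].
#' @param out_dir If non-`NULL`, result tables are written there as CSV,
#'   fitted models and the run manifest as JSON.
#' @param seed Seed recorded in the manifest and used for simulation.
#' @return A list with elements `horizons`, `pairs`, `sliced`, `ipa`,
#'   `ipa_ratios`, `slice_fits`, `converged`, `profile_models`,
#'   `ipa_convergence`, `depth_diffs`, `manifest`.
#' @export
run_pipeline <- function(horizons = NULL, pairs = NULL,
                         synthetic = synthetic_config(),
                         properties = c("particle_size_mm",
                                        "carbon_g_per_kg"),
                         floors = ipa_floors(),
                         model = color_carbon_model(),
                         predict_all = FALSE,
                         direction = "ratio_on_reference",
                         depths = c(0, 50, 100, 150),
                         out_dir = NULL, seed = NULL) {
  known <- c("particle_size_mm", "carbon_g_per_kg")
  bad <- setdiff(properties, known)
  if (length(bad)) {
    stop("unknown propert", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "), "; known: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  simulated <- is.null(horizons)
  if (simulated) {
    if (!is.null(seed)) synthetic$seed <- seed
    ds <- generate_dataset(synthetic)
    horizons <- ds$horizons
    pairs <- ds$pairs
  } else {
    if (is.null(pairs)) stop("pairs required when horizons are supplied",
                             call. = FALSE)
    horizons <- check_horizon_cols(horizons)
  }
  pairs <- pair_profiles(horizons, pairs)

  sliced <- lapply(setNames(properties, properties), function(p) {
    slice_profiles(horizons, p, model = model, predict_all = predict_all)
  })
  ipa <- dplyr::bind_rows(lapply(sliced, compute_ipa)) |>
    apply_ipa_floor(floors)
  ratios <- ipa_ratios(ipa, pairs)

  slice_fits <- lapply(sliced, function(s) {
    fit_slice_regressions(slice_ratio_table(s, pairs), direction = direction)
  })
  converged <- lapply(slice_fits, build_converged_profile)
  profile_models <- list()
  if ("particle_size_mm" %in% properties) {
    profile_models$particle_size <-
      fit_polynomial_profile(converged$particle_size_mm)
  }
  if ("carbon_g_per_kg" %in% properties) {
    profile_models$carbon <- fit_exponential_profile(converged$carbon_g_per_kg)
  }
  ipa_conv <- lapply(setNames(properties, properties), function(p) {
    ipa_convergence_regression(dplyr::filter(ratios, .data$property == p))
  })
  diffs <- lapply(sliced, function(s) depth_differences(s, pairs, depths))

  manifest <- list(
    package = "pedoconverge",
    version = as.character(utils::packageVersion("pedoconverge")),
    r_version = as.character(getRversion()),
    seed = if (simulated) synthetic$seed else seed,
    simulated = simulated,
    n_pairs = nrow(pairs),
    properties = properties,
    floors = floors,
    direction = direction,
    config_hash = rlang::hash(list(properties, floors, direction, depths,
                                   predict_all,
                                   if (simulated) unclass(synthetic)))
  )
  result <- list(horizons = horizons, pairs = pairs, sliced = sliced,
                 ipa = ipa, ipa_ratios = ratios, slice_fits = slice_fits,
                 converged = converged, profile_models = profile_models,
                 ipa_convergence = ipa_conv, depth_diffs = diffs,
                 manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_horizon_table(result$horizons, file.path(out_dir, "horizons.csv"))
  readr::write_csv(result$pairs, file.path(out_dir, "pairs.csv"))
  readr::write_csv(result$ipa, file.path(out_dir, "ipa.csv"))
  readr::write_csv(result$ipa_ratios, file.path(out_dir, "ipa_ratios.csv"))
  for (p in names(result$slice_fits)) {
    readr::write_csv(result$slice_fits[[p]],
                     file.path(out_dir, paste0("slice_fits_", p, ".csv")))
    readr::write_csv(tibble::as_tibble(result$converged[[p]]),
                     file.path(out_dir, paste0("converged_profile_", p,
                                               ".csv")))
    readr::write_csv(result$depth_diffs[[p]],
                     file.path(out_dir, paste0("depth_differences_", p,
                                               ".csv")))
  }
  models <- list()
  if (!is.null(result$profile_models$particle_size)) {
    pm <- result$profile_models$particle_size
    models$particle_size_polynomial <- list(
      coefficients = as.list(pm$coefficients),
      adj_r_squared = pm$adj_r_squared, basis = pm$basis)
  }
  if (!is.null(result$profile_models$carbon)) {
    cm <- result$profile_models$carbon
    models$carbon_exponential <- list(surface_value_g_kg = cm$surface_value,
                                      decay_rate_per_cm = cm$decay_rate)
  }
  models$ipa_convergence <- lapply(result$ipa_convergence, function(x) {
    list(intercept = x$intercept, slope = x$slope,
         f_statistic = x$f_statistic, df = x$df, p_value = x$p_value,
         n_pairs = x$n_pairs, converged_ipa = x$converged_ipa)
  })
  jsonlite::write_json(models, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
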