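# Builders for small in-code fixtures.

# One pedon's horizon rows from parallel vectors.
make_horizons <- function(pedon_id = "P1", condition = "reference",
                          top = 0, bottom = 150,
                          texture = NA_character_, munsell = NA_real_,
                          carbon = NA_real_, city = "cityA") {
  n <- max(length(top), length(bottom))
  tibble::tibble(
    pedon_id = pedon_id, condition = condition, city = city,
    land_use = NA_character_,
    top_cm = rep_len(top, n), bottom_cm = rep_len(bottom, n),
    texture_class = rep_len(texture, n),
    munsell_value = rep_len(munsell, n),
    carbon_g_kg = rep_len(carbon, n)
  )
}

# A sliced-profile tibble directly from a numeric vector of slice values.
make_sliced <- function(values, pedon_id = "P1",
                        property = "carbon_g_per_kg") {
  tibble::tibble(pedon_id = pedon_id, property = property,
                 depth_cm = seq_along(values) - 1L, value = values,
                 depth_available = sum(!is.na(values)))
}

# Paired urban/reference slice values following the multiplicative pull
# model exactly (no noise): ln u = (1 - b) ln c_star + b ln r.
pull_rows <- function(ln_reference, b, c_star, depth_cm = 0L) {
  tibble::tibble(
    depth_cm = depth_cm,
    urban_pedon_id = paste0("U", seq_along(ln_reference)),
    reference_pedon_id = paste0("R", seq_along(ln_reference)),
    property = "particle_size_mm",
    ln_reference = ln_reference,
    ln_ratio = (1 - b) * (log(c_star) - ln_reference)
  )
}
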