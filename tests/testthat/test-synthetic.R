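test_that("generated profiles are valid and datasets reproducible", {
  cfg <- synthetic_config(n_pairs = 6, seed = 99)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(validate_profiles(ds$horizons)), 0)
  expect_equal(dplyr::n_distinct(ds$horizons$pedon_id), 12)
  expect_equal(nrow(ds$pairs), 6)

  ds2 <- generate_dataset(cfg)
  expect_identical(ds$horizons, ds2$horizons)
  expect_identical(ds$pairs, ds2$pairs)

  # per-pair substreams: the first pair is unchanged when n_pairs grows
  ds3 <- generate_dataset(synthetic_config(n_pairs = 2, seed = 99))
  expect_identical(
    dplyr::filter(ds$horizons, pedon_id %in% c("R0001", "U0001")),
    dplyr::filter(ds3$horizons, pedon_id %in% c("R0001", "U0001")))
})

test_that("dataset scales to the study size", {
  ds <- generate_dataset(synthetic_config(n_pairs = 332, seed = 5))
  expect_equal(dplyr::n_distinct(ds$horizons$pedon_id), 664)
  expect_equal(dplyr::n_distinct(ds$horizons$city), 11)
})

test_that("truth object records the pull-model algebra", {
  cfg <- synthetic_config(n_pairs = 2, seed = 1, pull_strength = 0.37)
  tr <- generate_dataset(cfg)$truth$slice_truth
  expect_equal(tr$intercept, (1 - tr$b) * log(tr$c_star), tolerance = 1e-12)
  expect_equal(unique(tr$slope), 0.37 - 1)
  expect_true(all(tr$c_star > 0))
})

test_that("zero-noise reference carbon stays within one Munsell step of the curve", {
  cfg <- synthetic_config(n_pairs = 1, seed = 17, noise_sd = 0)
  withr::with_seed(123, {
    ref <- generate_reference_profile(cfg)
  })
  params <- attr(ref, "params")
  s <- slice_profiles(ref, "carbon_g_per_kg")
  mid <- s$depth_cm + 0.5
  truth <- params$carbon_surface * exp(-params$carbon_decay * mid)
  # only where the integer chip was not clipped at the range ends
  chip <- (5.07 - log(truth)) / 0.58
  inside <- chip > 2 & chip < 8
  err <- abs(log(s$value[inside]) - log(truth[inside]))
  # bound: half a Munsell step of quantization, plus the within-horizon
  # drift of the exponential curve away from the horizon midpoint
  half_thick <- max(ref$bottom_cm - ref$top_cm) / 2
  expect_lte(max(err), 0.58 / 2 + params$carbon_decay * half_thick + 1e-9)
})

test_that("reference texture shows the clay bulge at intermediate depth", {
  cfg <- synthetic_config(n_pairs = 1, seed = 1)
  set.seed(2024)
  at0 <- numeric(300); at50 <- numeric(300)
  for (i in 1:300) {
    ref <- generate_reference_profile(cfg)
    ps <- slice_profiles(ref, "particle_size_mm")
    at0[i] <- ps$value[ps$depth_cm == 0]
    at50[i] <- ps$value[ps$depth_cm == 50]
  }
  expect_lt(mean(at50), mean(at0))
})

test_that("pull strength endpoints behave as the model dictates", {
  # b = 1, zero noise: urbanization is the identity at slice level
  cfg1 <- synthetic_config(n_pairs = 3, seed = 8, pull_strength = 1,
                           noise_sd = 0)
  ds1 <- generate_dataset(cfg1)
  for (p in c("particle_size_mm", "carbon_g_per_kg")) {
    s <- slice_profiles(ds1$horizons, p)
    u <- dplyr::filter(s, grepl("^U", pedon_id)) |>
      dplyr::arrange(pedon_id, depth_cm)
    r <- dplyr::filter(s, grepl("^R", pedon_id)) |>
      dplyr::arrange(pedon_id, depth_cm)
    expect_equal(u$value, r$value, tolerance = 1e-12)
  }

  # b = 0, zero noise: urban equals the encoded convergence target everywhere
  cfg0 <- synthetic_config(n_pairs = 2, seed = 8, pull_strength = 0,
                           noise_sd = 0)
  ds0 <- generate_dataset(cfg0)
  urb <- dplyr::filter(ds0$horizons, condition == "urban")
  mid <- (urb$top_cm + urb$bottom_cm) / 2
  cstar_ps <- pedoconverge:::synthetic_cstar(cfg0, "particle_size_mm", mid)
  expect_equal(urb$texture_class,
               pedoconverge:::encode_texture_class(cstar_ps))
  cstar_c <- pedoconverge:::synthetic_cstar(cfg0, "carbon_g_per_kg", mid)
  expect_equal(urb$munsell_value,
               as.numeric(pedoconverge:::encode_munsell(cstar_c, cfg0)))

  # b = 0.5: urban lies between reference and target in log space
  cfg5 <- synthetic_config(n_pairs = 3, seed = 8, pull_strength = 0.5,
                           noise_sd = 0)
  ds5 <- generate_dataset(cfg5)
  s <- slice_profiles(ds5$horizons, "carbon_g_per_kg")
  u <- dplyr::filter(s, grepl("^U", pedon_id)) |>
    dplyr::arrange(pedon_id, depth_cm)
  r <- dplyr::filter(s, grepl("^R", pedon_id)) |>
    dplyr::arrange(pedon_id, depth_cm)
  cstar <- pedoconverge:::synthetic_cstar(cfg5, "carbon_g_per_kg",
                                          u$depth_cm + 0.5)
  lo <- pmin(log(r$value), log(cstar))
  hi <- pmax(log(r$value), log(cstar))
  # allow one Munsell quantization step beyond the exact log interval
  expect_true(all(log(u$value) >= lo - 0.29 & log(u$value) <= hi + 0.29))
})

test_that("null pull produces no spurious convergence", {
  cfg <- synthetic_config(n_pairs = 40, seed = 31, pull_strength = 1,
                          noise_sd = 0)
  ds <- generate_dataset(cfg)
  s <- slice_profiles(ds$horizons, "particle_size_mm")
  fits <- fit_slice_regressions(slice_ratio_table(s, ds$pairs))
  expect_true(all(abs(fits$slope[fits$fitted]) < 1e-9))
  expect_true(all(is.na(fits$convergence_point)))
})
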