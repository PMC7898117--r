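test_that("slice ratio table computes pairwise log ratios and exclusions", {
  ref <- make_sliced(rep(c(10, 20), each = 75), pedon_id = "R1")
  urb_same <- make_sliced(rep(c(10, 20), each = 75), pedon_id = "U1")
  pairs <- tibble::tibble(urban_pedon_id = "U1", reference_pedon_id = "R1")
  rows <- slice_ratio_table(dplyr::bind_rows(ref, urb_same), pairs)
  expect_equal(nrow(rows), 150)
  expect_equal(rows$ln_ratio, rep(0, 150))
  expect_equal(rows$ln_reference, log(rep(c(10, 20), each = 75)))

  urb2 <- make_sliced(c(20, rep(c(10, 20), each = 75)[-1]), pedon_id = "U1")
  rows2 <- slice_ratio_table(dplyr::bind_rows(ref, urb2), pairs)
  expect_equal(rows2$ln_ratio[rows2$depth_cm == 0], log(2))

  # missing or non-positive slices are excluded pairwise and counted
  urb3 <- make_sliced(c(NA, rep(5, 149)), pedon_id = "U1")
  rows3 <- slice_ratio_table(dplyr::bind_rows(ref, urb3), pairs)
  expect_equal(nrow(rows3), 149)
  expect_equal(attr(rows3, "n_excluded"), 1)
})

test_that("swapping urban and reference negates every log ratio", {
  set.seed(404)
  ref <- make_sliced(rlnorm(150, 2, 0.4), pedon_id = "R1")
  urb <- make_sliced(rlnorm(150, 2, 0.4), pedon_id = "U1")
  pairs <- tibble::tibble(urban_pedon_id = "U1", reference_pedon_id = "R1")
  fwd <- slice_ratio_table(dplyr::bind_rows(ref, urb), pairs)
  # swap roles: relabel pedons so the reference becomes urban and vice versa
  ref2 <- dplyr::mutate(urb, pedon_id = "R1")
  urb2 <- dplyr::mutate(ref, pedon_id = "U1")
  rev <- slice_ratio_table(dplyr::bind_rows(ref2, urb2), pairs)
  expect_equal(rev$ln_ratio, -fwd$ln_ratio, tolerance = 1e-12)
})

test_that("noiseless pull-model rows are fitted exactly", {
  set.seed(505)
  rows <- pull_rows(ln_reference = log(rlnorm(40, -2.5, 0.6)), b = 0.3,
                    c_star = 0.05)
  fit <- suppressWarnings(fit_slice_regressions(rows))
  expect_equal(fit$slope, -0.7, tolerance = 1e-9)
  expect_equal(fit$intercept, 0.7 * log(0.05), tolerance = 1e-9)
  expect_equal(fit$convergence_point, 0.05, tolerance = 1e-9)
  expect_true(fit$fitted)

  # intercept 0 (c_star = 1) puts the convergence point at reference = 1
  rows1 <- pull_rows(log(rlnorm(40, 0, 0.5)), b = 0.4, c_star = 1)
  expect_equal(suppressWarnings(fit_slice_regressions(rows1))$convergence_point, 1,
               tolerance = 1e-9)

  # b = 1: all ratios 0, slope exactly 0, point undefined and flagged
  rows0 <- pull_rows(log(rlnorm(40, -2.5, 0.6)), b = 1, c_star = 0.05)
  f0 <- suppressWarnings(fit_slice_regressions(rows0))
  expect_true(is.na(f0$convergence_point))
  expect_match(f0$flag, "slope 0")
})

test_that("degenerate and underpopulated depths are flagged, not fitted", {
  rows <- pull_rows(rep(log(0.1), 5), b = 0.3, c_star = 0.05)
  f <- fit_slice_regressions(rows)
  expect_false(f$fitted)
  expect_match(f$flag, "degenerate")
  f2 <- fit_slice_regressions(pull_rows(log(c(0.1, 0.2)), 0.3, 0.05))
  expect_false(f2$fitted)
  expect_match(f2$flag, "fewer than 3")
})

test_that("convergence_point reproduces published-coefficient levels", {
  # exp(3.15/0.81) and exp(3.58/0.90), frozen from hand evaluation
  expect_equal(convergence_point(3.15, -0.81), 48.8566, tolerance = 1e-4)
  expect_equal(convergence_point(3.58, -0.90), 53.3973, tolerance = 1e-4)
  expect_equal(convergence_point(0, -2), 1)
  expect_equal(convergence_point(0, 5), 1)
  expect_error(convergence_point(1, 0), "undefined")
})

test_that("convergence point rescales exactly with reference units", {
  set.seed(606)
  rows <- pull_rows(log(rlnorm(60, -2.5, 0.5)), b = 0.45, c_star = 0.05)
  rows <- dplyr::mutate(rows,
                        ln_ratio = ln_ratio + rnorm(60, 0, 0.05))
  base <- fit_slice_regressions(rows)
  for (k in c(0.1, 25.4)) {
    scaled <- dplyr::mutate(rows, ln_reference = ln_reference + log(k))
    res <- fit_slice_regressions(scaled)
    expect_equal(res$convergence_point, k * base$convergence_point,
                 tolerance = 1e-9)
  }
})

test_that("transposed regression direction is available", {
  set.seed(607)
  rows <- pull_rows(log(rlnorm(50, -2.5, 0.5)), b = 0.45, c_star = 0.05)
  rows <- dplyr::mutate(rows, ln_ratio = ln_ratio + rnorm(50, 0, 0.05))
  tr <- fit_slice_regressions(rows, direction = "reference_on_ratio")
  fit <- lm(ln_reference ~ ln_ratio, data = rows)
  expect_equal(tr$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_equal(tr$convergence_point, exp(unname(coef(fit)[1])),
               tolerance = 1e-12)
})

test_that("converged profile preserves gaps and enforces minimum support", {
  fits <- tibble::tibble(
    depth_cm = 0:19, property = "particle_size_mm",
    convergence_point = c(rep(0.05, 15), NA, 0.04, NA, 0.04, 0.05))
  cp <- build_converged_profile(fits)
  expect_s3_class(cp, "converged_profile")
  expect_equal(sum(is.na(cp$point)), 2)
  expect_equal(attr(cp, "property"), "particle_size_mm")
  few <- tibble::tibble(depth_cm = 0:9, property = "particle_size_mm",
                        convergence_point = c(rep(0.05, 5), rep(NA, 5)))
  expect_error(build_converged_profile(few), "at least 10")
})

test_that("quartic profile model interpolates exact quartics and is reproducible", {
  x <- 0:149
  z <- x / 150
  ln_true <- -3 + 0.8 * z - 2.1 * z^2 + 1.4 * z^3 - 0.4 * z^4
  cp <- build_converged_profile(tibble::tibble(
    depth_cm = x, property = "particle_size_mm",
    convergence_point = exp(ln_true)))
  pm <- suppressWarnings(fit_polynomial_profile(cp))
  expect_equal(pm$adj_r_squared, 1, tolerance = 1e-9)
  expect_equal(predict(pm, x), exp(ln_true), tolerance = 1e-9)
  expect_equal(length(pm$coefficients), 5)

  # constant profile: all depth terms vanish
  cpc <- build_converged_profile(tibble::tibble(
    depth_cm = x, property = "particle_size_mm",
    convergence_point = rep(0.06, 150)))
  pmc <- suppressWarnings(fit_polynomial_profile(cpc))
  expect_equal(unname(pmc$coefficients[-1]), rep(0, 4), tolerance = 1e-9)

  # noisy quartic: adjusted R^2 matches an independent raw-basis recomputation
  set.seed(707)
  noisy <- exp(ln_true + rnorm(150, 0, 0.1))
  cpn <- build_converged_profile(tibble::tibble(
    depth_cm = x, property = "particle_size_mm", convergence_point = noisy))
  pmn <- fit_polynomial_profile(cpn)
  X <- cbind(1, z, z^2, z^3, z^4)
  beta <- solve(crossprod(X), crossprod(X, log(noisy)))
  res <- log(noisy) - X %*% beta
  tss <- sum((log(noisy) - mean(log(noisy)))^2)
  adj <- 1 - (sum(res^2) / (150 - 5)) / (tss / 149)
  expect_equal(pmn$adj_r_squared, adj, tolerance = 1e-8)
})

test_that("exponential carbon model recovers generating parameters", {
  x <- 0:149
  pts <- 18.4 * exp(-0.005868 * x)
  cp <- build_converged_profile(tibble::tibble(
    depth_cm = x, property = "carbon_g_per_kg", convergence_point = pts))
  em <- fit_exponential_profile(cp)
  expect_equal(em$surface_value, 18.4, tolerance = 1e-7)
  expect_equal(em$decay_rate, 0.005868, tolerance = 1e-7)
  expect_equal(predict(em, 50), 18.4 * exp(-0.005868 * 50), tolerance = 1e-6)

  # constant points: surface value c, decay 0
  cpc <- build_converged_profile(tibble::tibble(
    depth_cm = x, property = "carbon_g_per_kg",
    convergence_point = rep(9, 150)))
  emc <- fit_exponential_profile(cpc)
  expect_equal(emc$surface_value, 9, tolerance = 1e-9)
  expect_equal(emc$decay_rate, 0, tolerance = 1e-9)

  # noisy exponential against a brute-force grid-search oracle
  set.seed(808)
  noisy <- 18.4 * exp(-0.005868 * x) * rlnorm(150, 0, 0.1)
  cpn <- build_converged_profile(tibble::tibble(
    depth_cm = x, property = "carbon_g_per_kg", convergence_point = noisy))
  emn <- fit_exponential_profile(cpn)
  grid <- expand.grid(Co = seq(15, 25, by = 0.05),
                      k = seq(0.002, 0.01, by = 0.00005))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((noisy - grid$Co[i] * exp(-grid$k[i] * x))^2)
  }, numeric(1))
  best <- grid[which.min(sse), ]
  expect_equal(emn$surface_value, best$Co, tolerance = 0.01)
  expect_equal(emn$decay_rate, best$k, tolerance = 0.02)
  # nls solution is at least as good as the best grid point
  expect_lte(sum((noisy - predict(emn, x))^2), min(sse) + 1e-9)

  # agreement with the closed-form log-linear fit in the noiseless limit
  loglin <- lm(log(pts) ~ x)
  expect_equal(em$surface_value, exp(unname(coef(loglin)[1])),
               tolerance = 1e-7)
  expect_equal(em$decay_rate, -unname(coef(loglin)[2]), tolerance = 1e-7)
})

test_that("depth differences are extracted at the stated depths", {
  ref <- make_sliced(seq(1, 2, length.out = 150), pedon_id = "R1",
                     property = "particle_size_mm")
  urb <- dplyr::mutate(ref, pedon_id = "U1")
  pairs <- tibble::tibble(urban_pedon_id = "U1", reference_pedon_id = "R1")
  d <- depth_differences(dplyr::bind_rows(ref, urb), pairs)
  expect_equal(d$depth_cm, c(0, 50, 100, 150))
  expect_equal(d$difference, rep(0, 4))

  urb2 <- dplyr::mutate(ref, pedon_id = "U1", value = value - 0.3)
  d2 <- depth_differences(dplyr::bind_rows(ref, urb2), pairs)
  expect_equal(d2$difference, rep(-0.3, 4), tolerance = 1e-12)
  # depth 150 reads the deepest slice (index 149)
  expect_equal(d2$reference_value[d2$depth_cm == 150],
               ref$value[ref$depth_cm == 149])
  expect_error(depth_differences(dplyr::bind_rows(ref, urb), pairs,
                                 depths = c(0, 200)), "within")
  s <- summarize_depth_differences(d2)
  expect_equal(s$mean_difference, rep(-0.3, 4), tolerance = 1e-12)
})

test_that("IPA-level convergence regression recovers the pull model", {
  set.seed(909)
  # pull toward IPA 48.8566 with slope -0.81 (so b = 0.19), no noise
  b <- 0.19
  target <- exp(3.15 / 0.81)
  ref_ipa <- exp(runif(80, log(13), log(200)))
  urb_ipa <- exp((1 - b) * log(target) + b * log(ref_ipa))
  ratios <- tibble::tibble(property = "particle_size_mm",
                           reference_ipa = ref_ipa, urban_ipa = urb_ipa)
  res <- ipa_convergence_regression(ratios)
  expect_equal(res$slope, -0.81, tolerance = 1e-9)
  expect_equal(res$intercept, 0.81 * log(target), tolerance = 1e-9)
  expect_equal(res$converged_ipa, target, tolerance = 1e-9)
  expect_equal(res$n_pairs, 80)
  expect_equal(unname(res$df[2]), 78)

  # all ratios 1 over varying reference: slope 0, no convergence point
  flat <- tibble::tibble(property = "carbon_g_per_kg",
                         reference_ipa = ref_ipa, urban_ipa = ref_ipa)
  rflat <- ipa_convergence_regression(flat)
  expect_equal(rflat$slope, 0, tolerance = 1e-12)
  expect_true(is.na(rflat$converged_ipa))

  expect_error(ipa_convergence_regression(ratios[1:2, ]), "at least 3")
  degen <- tibble::tibble(reference_ipa = rep(50, 5),
                          urban_ipa = rlnorm(5, 3, 0.2))
  expect_error(ipa_convergence_regression(degen), "degenerate")

  td <- tidy(res)
  expect_equal(td$estimate, c(res$intercept, res$slope))
  gl <- glance(res)
  expect_equal(gl$converged_ipa, res$converged_ipa)
})

test_that("IPA regression slope estimates center on the generating slope", {
  s <- -0.81
  est <- vapply(1:20, function(r) {
    set.seed(1000 + r)
    ln_ref <- runif(206, log(13), log(200))
    ln_ratio <- 3.15 + s * ln_ref + rnorm(206, 0, 0.3)
    ipa_convergence_regression(tibble::tibble(
      reference_ipa = exp(ln_ref),
      urban_ipa = exp(ln_ref + ln_ratio)))$slope
  }, numeric(1))
  expect_lt(abs(mean(est) - s), 0.05)
})
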