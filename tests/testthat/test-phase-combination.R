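test_that("resolution binning is equal-count, ordered and merge-safe", {
  toy <- small_toy()
  b1 <- assign_bins(toy$refl, 1)
  expect_true(all(b1$bin == 1))

  b4 <- assign_bins(toy$refl, 4)
  expect_lte(diff(range(b4$counts)), 1)
  s2 <- 1 / toy$refl$d^2
  expect_true(all(diff(vapply(1:4, function(b) max(s2[b4$bin == b]),
                              numeric(1))) > 0))
  # bins are contiguous in resolution
  expect_true(all(vapply(1:3, function(b)
    max(s2[b4$bin == b]) <= min(s2[b4$bin == b + 1]), logical(1))))

  expect_warning(assign_bins(toy$refl[1:120, ], 10), "merging")
})

test_that("Luzzati refinement recovers planted D and detects null models", {
  set.seed(42)
  # parameter recovery from Rice-simulated data, one bin of 5000
  d_true <- 0.7
  sigma_sq <- 100
  est <- replicate(3, {
    fc <- rwilson_amp(5000, sigma_sq)
    fo <- rrice_obs(fc, d_true, sigma_sq * (1 - d_true^2))
    refine_luzzati(fo, fc, rep(1L, 5000))$d
  })
  expect_lt(abs(mean(est) - d_true), 0.03)

  # perfect model: D near 1, vanishing residual variance
  fc <- rwilson_amp(3000, sigma_sq)
  fit <- refine_luzzati(fc, fc, rep(1L, 3000))
  expect_gt(fit$d, 0.98)
  expect_lt(fit$sigma2, 1e-3 * sigma_sq)

  # independent model: D indistinguishable from zero
  fc2 <- rwilson_amp(5000, sigma_sq)
  fo2 <- rwilson_amp(5000, sigma_sq)
  fit2 <- refine_luzzati(fo2, fc2, rep(1L, 5000))
  expect_lt(fit2$d, 0.1)
})

test_that("beta scaling of the covariance model is exact and monotone", {
  luz <- manual_cov(d = 0.8, sigma2 = 36, mean_fc2 = 100, beta = 1)
  expect_equal(luz$d_eff, 0.8)
  expect_equal(luz$sigma2_eff, 36)

  half <- manual_cov(d = 0.8, sigma2 = 36, mean_fc2 = 100, beta = 0.5)
  expect_equal(half$d_eff, 0.4)
  expect_equal(half$sigma2_eff, 36 + (1 - 0.25) * 0.64 * 100)
  expect_error(manual_cov(beta = -1), "beta")

  # weaker model weight gives lower combined FOM on identical inputs
  toy <- small_toy()
  n <- nrow(toy$refl)
  fc_amp <- toy$refl$fo * 0.9
  fc_phi <- toy$refl$phi_true
  bin <- rep(1L, n)
  luz1 <- refine_luzzati(toy$refl$fo, fc_amp, bin)
  c1 <- combine_phases(toy$phases, toy$refl$fo, fc_amp, fc_phi, bin,
                       apply_beta(luz1, 1))
  c05 <- combine_phases(toy$phases, toy$refl$fo, fc_amp, fc_phi, bin,
                        apply_beta(luz1, 0.5))
  expect_lt(mean(c05$fom), mean(c1$fom))
})

test_that("phase combination has correct limits and closed-form behaviour", {
  toy <- small_toy()
  n <- nrow(toy$refl)
  bin <- rep(1L, n)
  fc_phi <- toy$refl$phi_true

  # zero model weight: distribution unchanged
  cov0 <- manual_cov(d = 0, sigma2 = 100, mean_fc2 = 100)
  c0 <- combine_phases(toy$phases, toy$refl$fo, toy$refl$fo, fc_phi, bin, cov0)
  expect_equal(c0$fom, toy$phases$fom, tolerance = 1e-9)
  expect_equal(c0$phi, toy$phases$phi, tolerance = 1e-6)

  # model-only limit: von Mises with concentration X
  blank <- toy$phases
  blank$hla <- blank$hlb <- blank$hlc <- blank$hld <- 0
  fo <- rep(10, n); fc <- rep(10, n)
  covx <- manual_cov(d = 0.6, sigma2 = 100, mean_fc2 = 100)  # X = 1.2
  cm <- combine_phases(blank, fo, fc, fc_phi, bin, covx)
  x <- 2 * 0.6 * 10 * 10 / 100
  expect_equal(cm$fom, rep(betadm:::bessel_ratio(x), n), tolerance = 1e-6)
  expect_equal(cm$phi, fc_phi, tolerance = 1e-6)

  # FOM monotone nondecreasing in X for a fixed experimental distribution
  foms <- vapply(seq(0, 5, by = 0.25), function(xx) {
    cv <- manual_cov(d = xx / 2, sigma2 = 100, mean_fc2 = 100)
    mean(combine_phases(toy$phases, rep(10, n), rep(10, n), toy$phases$phi,
                        bin, cv)$fom)
  }, numeric(1))
  expect_true(all(diff(foms) >= -1e-9))
})

test_that("360-point quadrature agrees with the unimodal closed form", {
  set.seed(77)
  n <- 500
  a <- stats::rnorm(n, 0, 3)
  b <- stats::rnorm(n, 0, 3)
  x <- stats::runif(n, 0, 10)
  phic <- stats::runif(n, -pi, pi)
  a2 <- a + x * cos(phic)
  b2 <- b + x * sin(phic)
  cen <- betadm:::hl_centroid(a2, b2, rep(0, n), rep(0, n))
  r <- sqrt(a2^2 + b2^2)
  expect_equal(cen$fom, betadm:::bessel_ratio(r), tolerance = 1e-6)
  dphi <- atan2(sin(cen$phi - atan2(b2, a2)), cos(cen$phi - atan2(b2, a2)))
  expect_lt(max(abs(dphi)), 1e-6)
})

test_that("quadrature is converged at 360 points", {
  set.seed(3)
  n <- 200
  a <- stats::rnorm(n, 0, 4); b <- stats::rnorm(n, 0, 4)
  cc <- stats::rnorm(n, 0, 1); dd <- stats::rnorm(n, 0, 1)
  c360 <- betadm:::hl_centroid(a, b, cc, dd, n_grid = 360)
  c3600 <- betadm:::hl_centroid(a, b, cc, dd, n_grid = 3600)
  expect_lt(max(abs(c360$fom - c3600$fom)), 1e-6)
})

test_that("map coefficient modes reduce correctly and flag bad input", {
  toy <- small_toy()
  n <- nrow(toy$refl)
  comb <- toy$phases
  comb$fom <- rep(1, n)
  comb$phi <- toy$refl$phi_true
  cov1 <- manual_cov(d = 1, sigma2 = 1, mean_fc2 = 100)
  refl <- toy$refl
  refl$bin <- 1L
  cen <- map_coefficients(comb, refl, cov1, "centroid")
  two <- map_coefficients(comb, refl, cov1, "2mfodfc", fc_amp = refl$fo)
  expect_equal(cen, two, tolerance = 1e-12)
  expect_equal(Mod(cen), refl$fo)

  comb$fom <- rep(0, n)
  expect_equal(Mod(map_coefficients(comb, refl, cov1, "centroid")), rep(0, n))
  expect_error(map_coefficients(comb, refl, cov1, "fancy"))
})

test_that("2mFo-DFc map is less correlated with the experimental map", {
  toy <- default_toy(kappa = 1, seed = 5)
  refl <- toy$refl
  cell <- attr(refl, "cell")
  grid <- default_grid(cell, min(refl$d))
  hkl <- refl[, c("h", "k", "l")]
  exp_map <- synthesize_map(hkl, toy$phases$fom * refl$fo *
                              exp(1i * toy$phases$phi), cell, grid)
  tr <- run_dm(refl, toy$phases, dm_options(n_cycles = 1))
  fin <- attr(tr, "final")
  refl$bin <- fin$bin
  cen_map <- synthesize_map(hkl, map_coefficients(fin$comb, refl, fin$cov,
                                                  "centroid"), cell, grid)
  two_map <- synthesize_map(hkl, map_coefficients(fin$comb, refl, fin$cov,
                                                  "2mfodfc"), cell, grid)
  expect_lt(map_correlation(two_map, exp_map), map_correlation(cen_map, exp_map))
})
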