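test_that("Wang mask flags the requested quantile and ignores map scale", {
  toy <- small_toy()
  refl <- toy$refl
  cell <- attr(refl, "cell")
  grid <- default_grid(cell, min(refl$d))
  m <- synthesize_map(refl[, c("h", "k", "l")], refl$f_true, cell, grid)

  mask <- wang_solvent_mask(m, 0.5, radius = 5)
  expect_lt(abs(mean(mask$solvent) - 0.5), 0.01)

  scaled <- density_map(4.2 * m$rho, cell)
  mask2 <- wang_solvent_mask(scaled, 0.5, radius = 5)
  expect_identical(mask$solvent, mask2$solvent)

  flat <- density_map(array(1, dim(m$rho)), cell)
  expect_error(wang_solvent_mask(flat, 0.5), "constant")
  expect_error(wang_solvent_mask(m, 1.2), "solvent_fraction")
})

test_that("Wang mask recovers a known protein region", {
  cell <- unit_cell(20, 20, 20)
  n <- 24
  fr <- (seq_len(n) - 1) / n
  d2 <- outer(outer(pmin(fr, 1 - fr)^2, pmin(fr, 1 - fr)^2, `+`),
              pmin(fr, 1 - fr)^2, `+`) * cell$a^2
  protein <- d2 <= 7.8^2                     # ball centred on the origin
  set.seed(5)
  rho <- array(stats::rnorm(n^3, 0, 0.05), c(n, n, n))
  rho[protein] <- rho[protein] + stats::rnorm(sum(protein), 0, 1)
  m <- density_map(rho, cell)
  mask <- wang_solvent_mask(m, 1 - mean(protein), radius = 4)
  agreement <- mean((!mask$solvent) == protein)
  expect_gt(agreement, 0.95)
})

test_that("solvent flattening zeroes solvent variance and nothing else", {
  toy <- small_toy()
  cell <- attr(toy$refl, "cell")
  grid <- default_grid(cell, min(toy$refl$d))
  m <- synthesize_map(toy$refl[, c("h", "k", "l")], toy$refl$f_true, cell, grid)

  all_solv <- manual_mask(array(TRUE, dim(m$rho)))
  flat <- solvent_flatten(m, all_solv)
  expect_equal(max(flat$rho) - min(flat$rho), 0)

  none_solv <- manual_mask(array(FALSE, dim(m$rho)))
  expect_equal(solvent_flatten(m, none_solv)$rho, m$rho)

  mask <- wang_solvent_mask(m, 0.4, radius = 5)
  out <- solvent_flatten(m, mask)
  expect_equal(stats::var(out$rho[mask$solvent]), 0)
  expect_equal(out$rho[!mask$solvent], m$rho[!mask$solvent])
})

test_that("histogram matching hits the target and preserves ranks", {
  toy <- small_toy()
  cell <- attr(toy$refl, "cell")
  grid <- default_grid(cell, min(toy$refl$d))
  m <- synthesize_map(toy$refl[, c("h", "k", "l")], toy$refl$f_true, cell, grid)
  mask <- wang_solvent_mask(m, 0.5, radius = 5)
  prot <- !mask$solvent

  # own histogram: near identity
  own <- density_histogram(m$rho[prot])
  ident <- histogram_match(m, mask, own)
  binw <- diff(own$edges[1:2]) * stats::sd(m$rho[prot])
  expect_lt(max(abs(ident$rho[prot] - m$rho[prot])), 2 * binw)
  expect_equal(ident$rho[mask$solvent], m$rho[mask$solvent])

  # foreign target: total variation distance of standardized histograms
  target <- default_protein_histogram()
  out <- histogram_match(m, mask, target)
  v <- out$rho[prot]
  z <- (v - mean(v)) / stats::sd(v)
  counts <- tabulate(findInterval(z, target$edges, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     length(target$probs))
  tv <- 0.5 * sum(abs(counts / sum(counts) - target$probs))
  expect_lt(tv, 0.02)

  # monotone: ranking within the protein region preserved
  expect_identical(order(out$rho[prot]), order(m$rho[prot]))

  tiny_mask <- manual_mask(array(c(FALSE, rep(TRUE, length(m$rho) - 1)),
                                 dim(m$rho)))
  expect_error(histogram_match(m, tiny_mask, target), "fewer protein voxels")
})

test_that("null modification is the identity, also through inversion", {
  toy <- small_toy()
  refl <- toy$refl
  cell <- attr(refl, "cell")
  grid <- default_grid(cell, min(refl$d))
  coeffs <- toy$phases$fom * refl$fo * exp(1i * toy$phases$phi)
  m <- synthesize_map(refl[, c("h", "k", "l")], coeffs, cell, grid)
  m2 <- null_modify(m)
  expect_equal(m2$rho, m$rho)
  back <- map_to_structure_factors(m2, refl[, c("h", "k", "l")])
  expect_equal(Mod(back), Mod(coeffs), tolerance = 1e-10)
})

test_that("run_dm honours its contract and is deterministic", {
  toy <- small_toy()
  opt <- dm_options(n_cycles = 3)
  tr <- run_dm(toy$refl, toy$phases, opt)
  expect_s3_class(tr, "dm_trace")
  expect_equal(nrow(tr), 3)
  expect_true(all(tr$mean_fom >= 0 & tr$mean_fom <= 1))
  expect_true(all(is.finite(tr$cpem)))

  tr2 <- run_dm(toy$refl, toy$phases, opt)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))

  expect_error(dm_options(ops = character(0)), "empty")
  expect_error(dm_options(n_cycles = 0), "n_cycles")
  expect_error(dm_options(ops = "sharpen"), "subset")
})

test_that("a single null cycle with full data inflates the average FOM", {
  toy <- small_toy()
  tr <- run_dm(toy$refl, toy$phases, dm_options(n_cycles = 1, ops = "null"))
  expect_gt(tr$mean_fom[1], mean(toy$phases$fom))
})

test_that("solvent flattening plus histogram matching improves a kappa=1 map", {
  toy <- default_toy(kappa = 1, seed = 5)
  tr <- run_dm(toy$refl, toy$phases, dm_options(n_cycles = 8))
  expect_gt(tr$map_cc[8], attr(tr, "initial_map_cc"))
  expect_gt(tr$cpem[8], 0)
})
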