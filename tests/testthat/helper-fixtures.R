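# Shared fixtures. Everything is generated in code; the cache avoids
# re-simulating the same toy crystal across test files.
.fixture_cache <- new.env(parent = emptyenv())

# compact toy for unit tests: ~700 reflections, 24^3 grid
small_toy <- function(kappa = 1, seed = 11) {
  key <- sprintf("small_%g_%d", kappa, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_toy_dataset(
      kappa, n_atoms = 40, cell = unit_cell(18, 18, 18), d_min = 2.6,
      noise = 0.05, seed = seed)
  .fixture_cache[[key]]
}

# full-size toy matching the package defaults (~2100 reflections)
default_toy <- function(kappa = 1, seed = 5) {
  key <- sprintf("default_%g_%d", kappa, seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_toy_dataset(kappa, seed = seed)
  .fixture_cache[[key]]
}

# minimal stand-in reflection table for statistical checks that only need
# f_true / phi_true and row count (no crystal needed)
flat_refl <- function(n, amp = 100) {
  refl <- data.frame(h = seq_len(n), k = 0L, l = 0L, d = 3,
                     fo = amp, sigfo = 1, phi_true = 0,
                     free = FALSE, bin = 1L)
  refl$f_true <- complex(modulus = amp, argument = 0)
  attr(refl, "cell") <- unit_cell(10, 10, 10)
  class(refl) <- c("refl_set", "data.frame")
  refl
}

# hand-built solvent mask
manual_mask <- function(solvent_array) {
  structure(list(solvent = solvent_array,
                 solvent_fraction = mean(solvent_array), radius = 0),
            class = "solvent_mask")
}

# hand-built covariance model for a single bin with a prescribed model
# weight: X = 2 d fo fc / sigma2
manual_cov <- function(d = 0.5, sigma2 = 100, mean_fc2 = 100, beta = 1) {
  luz <- data.frame(bin = 1L, d = d, sigma2 = sigma2, mean_fc2 = mean_fc2,
                    n = 1000L)
  class(luz) <- c("luzzati_model", "data.frame")
  apply_beta(luz, beta)
}

# acentric Wilson amplitudes and Rice-distributed observations, used as
# simulation truth for the Luzzati recovery checks
rwilson_amp <- function(n, sigma_sq = 100) sqrt(stats::rexp(n, 1 / sigma_sq))

rrice_obs <- function(fc, d_true, sigma_delta2) {
  n <- length(fc)
  re <- stats::rnorm(n, d_true * fc, sqrt(sigma_delta2 / 2))
  im <- stats::rnorm(n, 0, sqrt(sigma_delta2 / 2))
  sqrt(re^2 + im^2)
}
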