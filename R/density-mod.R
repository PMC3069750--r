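#' Wang-style solvent mask from local density smoothness
#'
#' Scores each voxel by the local mean of |rho| within a sphere of the given
#' radius (periodic convolution, computed by FFT) and flags the fraction
#' `solvent_fraction` of voxels with the lowest score as solvent. Protein
#' regions carry strong local density variation, disordered solvent does
#' not, so the low-score quantile tracks the solvent region.
#'
#' @param map A [density_map()].
#' @param solvent_fraction Fraction of the cell treated as solvent, in (0,1).
#' @param radius Smoothing sphere radius in Angstrom (default 8).
#' @return Object of class `solvent_mask`: logical array `solvent` (TRUE =
#'   solvent voxel) plus the requested fraction and radius.
#' @export
wang_solvent_mask <- function(map, solvent_fraction, radius = 8) {
  stopifnot(inherits(map, "density_map"))
  if (solvent_fraction <= 0 || solvent_fraction >= 1)
    stop("solvent_fraction must lie in (0, 1)")
  if (radius <= 0) stop("radius must be positive")
  rho <- map$rho
  if (max(rho) - min(rho) < 1e-12 * (abs(mean(rho)) + 1))
    stop("constant map cannot be partitioned into solvent and protein")
  score <- sphere_smooth(abs(rho), map$cell, radius)
  n_solv <- floor(solvent_fraction * length(score))
  cut <- sort(as.vector(score), partial = n_solv)[n_solv]
  solvent <- array(score <= cut, dim(rho))
  # ties at the threshold could overshoot; trim deterministically
  excess <- sum(solvent) - n_solv
  if (excess > 0) {
    at_cut <- which(score == cut)
    solvent[at_cut[seq_len(excess)]] <- FALSE
  }
  structure(list(solvent = solvent, solvent_fraction = solvent_fraction,
                 radius = radius), class = "solvent_mask")
}

# periodic convolution with a normalized spherical kernel (FFT based)
sphere_smooth <- function(arr, cell, radius) {
  d <- dim(arr)
  ax <- c(cell$a, cell$b, cell$c)
  # minimum-image distances of each grid offset from the origin, per axis
  dist1 <- function(n, len) {
    f <- (seq_len(n) - 1) / n
    pmin(f, 1 - f) * len
  }
  dx2 <- dist1(d[1], ax[1])^2
  dy2 <- dist1(d[2], ax[2])^2
  dz2 <- dist1(d[3], ax[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  kern <- array(as.numeric(r2 <= radius^2), d)
  conv <- Re(stats::fft(stats::fft(arr) * stats::fft(kern), inverse = TRUE)) /
    prod(d)
  conv / sum(kern)
}

#' Flatten the solvent region of a map
#'
#' Sets every solvent voxel to the mean density of the solvent region;
#' protein voxels are untouched.
#'
#' @param map A [density_map()].
#' @param mask A [wang_solvent_mask()] on the same grid.
#' @return The flattened [density_map()], labelled "modified".
#' @export
solvent_flatten <- function(map, mask) {
  stopifnot(inherits(map, "density_map"), inherits(mask, "solvent_mask"))
  if (!identical(dim(map$rho), dim(mask$solvent)))
    stop("mask and map grids differ")
  rho <- map$rho
  if (any(mask$solvent)) rho[mask$solvent] <- mean(rho[mask$solvent])
  density_map(rho, map$cell, "modified")
}

#' Standardized density histogram of a map region
#'
#' Computes the empirical histogram of the selected voxels after
#' standardization to zero mean and unit variance. Used as the target for
#' [histogram_match()].
#'
#' @param values Numeric vector of density samples (e.g. protein-region
#'   voxels of a reference map).
#' @param n_bins Number of histogram bins.
#' @return Object of class `density_histogram` with standardized bin `edges`
#'   and `probs` (non-negative, summing to one).
#' @export
density_histogram <- function(values, n_bins = 40) {
  stopifnot(length(values) > n_bins, n_bins >= 2)
  z <- (values - mean(values)) / stats::sd(values)
  rng <- range(z)
  edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  counts <- tabulate(findInterval(z, edges, rightmost.closed = TRUE), n_bins)
  structure(list(edges = edges, probs = counts / sum(counts)),
            class = "density_histogram")
}

# inverse CDF of a density_histogram (piecewise linear within bins)
histogram_quantile <- function(hist, p) {
  cum <- c(0, cumsum(hist$probs))
  cum[length(cum)] <- 1
  # collapse zero-probability plateaus so approx() gets strictly increasing x
  keep <- c(TRUE, diff(cum) > 0)
  stats::approx(cum[keep], hist$edges[keep], xout = pmin(pmax(p, 0), 1),
                ties = "ordered", rule = 2)$y
}

#' Default protein density histogram
#'
#' Standardized density histogram of the protein region of a reference toy
#' crystal (60 point atoms in a 22 Angstrom P1 cell at 2.2 Angstrom
#' resolution), built deterministically in code. Serves as the histogram-
#' matching target when no ground-truth map is available.
#'
#' @return A [density_histogram()].
#' @export
default_protein_histogram <- function() {
  cached_default_histogram()
}

.betadm_cache <- new.env(parent = emptyenv())

cached_default_histogram <- function() {
  if (is.null(.betadm_cache$hist))
    .betadm_cache$hist <- build_default_histogram()
  .betadm_cache$hist
}

build_default_histogram <- function() {
  cell <- unit_cell(22, 22, 22)
  model <- generate_toy_structure(60, cell, seed = 20110318)
  refl <- direct_structure_factors(model, 2.2)
  map <- synthesize_map(refl[, c("h", "k", "l")], refl$f_true, cell,
                        default_grid(cell, 2.2), label = "model")
  mask <- wang_solvent_mask(map, 0.5)
  density_histogram(map$rho[!mask$solvent])
}

#' Match the protein-region density distribution to a target histogram
#'
#' Applies the monotone rank-preserving transform that carries the empirical
#' distribution of the protein-region voxels onto `target`. Matching is done
#' in standardized units; the original protein-region mean and standard
#' deviation are restored afterwards so the overall map scale is stable
#' across cycles. Solvent voxels are untouched.
#'
#' @param map A [density_map()].
#' @param mask A [wang_solvent_mask()]; protein region is its complement.
#' @param target A [density_histogram()].
#' @return The matched [density_map()], labelled "modified".
#' @export
histogram_match <- function(map, mask, target) {
  stopifnot(inherits(map, "density_map"), inherits(mask, "solvent_mask"),
            inherits(target, "density_histogram"))
  if (!identical(dim(map$rho), dim(mask$solvent)))
    stop("mask and map grids differ")
  prot <- !mask$solvent
  v <- map$rho[prot]
  if (length(v) <= length(target$probs))
    stop("fewer protein voxels than histogram bins")
  m <- mean(v); s <- stats::sd(v)
  p <- (rank(v, ties.method = "first") - 0.5) / length(v)
  z_new <- histogram_quantile(target, p)
  # restandardize the matched values, then restore the original moments
  z_new <- (z_new - mean(z_new)) / stats::sd(z_new)
  rho <- map$rho
  rho[prot] <- m + s * z_new
  density_map(rho, map$cell, "modified")
}

#' Null density modification
#'
#' Returns the map unchanged. Useless as a map improver, but the standard
#' stress test for bias control: with the modified map identical to the
#' input, any apparent gain in figure of merit is pure statistical bias.
#'
#' @param map A [density_map()].
#' @return The same map, relabelled "modified".
#' @export
null_modify <- function(map) {
  stopifnot(inherits(map, "density_map"))
  density_map(map$rho, map$cell, "modified")
}

#' Options for the density-modification engine
#'
#' @param n_cycles Number of density-modification cycles (default 20).
#' @param ops Character vector of real-space operators applied in order,
#'   subset of "flatten", "histmatch", "null".
#' @param mode Map-coefficient mode for the next-cycle map: "2mfodfc"
#'   (default, model-bias suppressing) or "centroid".
#' @param beta Covariance correction factor applied after Luzzati-D
#'   refinement each cycle; 1 means no correction.
#' @param use_free "use_all" (default) or "exclude_free": whether
#'   free-flagged reflections enter D refinement and map synthesis.
#' @param solvent_fraction Solvent fraction for the Wang mask.
#' @param mask_radius Wang mask smoothing radius in Angstrom.
#' @param n_bins Number of resolution bins for D refinement (NULL = choose
#'   from the reflection count, at least 50 reflections per bin).
#' @param grid Map grid dimensions (NULL = [default_grid()]).
#' @param target_histogram Histogram-matching target (NULL = the reference
#'   [default_protein_histogram()], mimicking the library histograms real
#'   density-modification programs ship; pass a truth-derived histogram
#'   explicitly for best-case experiments).
#' @param est_cycles Cycles used for beta estimation in
#'   [run_beta_corrected_dm()] (default 5).
#' @param free_fraction,free_scheme,free_seed Free-set selection used by
#'   [run_beta_corrected_dm()] when the reflection set carries no flags.
#' @return A classed options list.
#' @export
dm_options <- function(n_cycles = 20, ops = c("flatten", "histmatch"),
                       mode = c("2mfodfc", "centroid"), beta = 1,
                       use_free = c("use_all", "exclude_free"),
                       solvent_fraction = 0.5, mask_radius = 8,
                       n_bins = NULL, grid = NULL, target_histogram = NULL,
                       est_cycles = 5, free_fraction = 0.05,
                       free_scheme = c("random", "thin_shells"),
                       free_seed = 42) {
  mode <- match.arg(mode)
  use_free <- match.arg(use_free)
  free_scheme <- match.arg(free_scheme)
  if (length(ops) < 1) stop("operator list must not be empty")
  if (!all(ops %in% c("flatten", "histmatch", "null")))
    stop("ops must be a subset of {flatten, histmatch, null}")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (!is.numeric(beta) || beta <= 0) stop("beta must be a positive number")
  structure(list(n_cycles = as.integer(n_cycles), ops = ops, mode = mode,
                 beta = beta, use_free = use_free,
                 solvent_fraction = solvent_fraction,
                 mask_radius = mask_radius, n_bins = n_bins, grid = grid,
                 target_histogram = target_histogram,
                 est_cycles = as.integer(est_cycles),
                 free_fraction = free_fraction, free_scheme = free_scheme,
                 free_seed = free_seed),
            class = "dm_options")
}

#' Run the classical density-modification loop
#'
#' Each cycle: synthesize a map from the current combined phase estimates,
#' apply the real-space operators, invert the modified map to model
#' structure factors, place them on the observed amplitude scale per
#' resolution bin, refine the Luzzati D (and residual variance) per bin by
#' the acentric Rice likelihood, scale the model covariance by `beta`, and
#' recombine with the original experimental phase distribution. The
#' experimental information is never overwritten: every cycle combines the
#' fresh model term with the original Hendrickson-Lattman coefficients.
#'
#' When the reflection set carries ground truth (`f_true`), the per-cycle
#' trace also records the mean cosine of the phase error (CPEM) and the
#' correlation of the combined map with the true map.
#'
#' @param refl Reflection set (see [direct_structure_factors()] or
#'   [read_reflections()]).
#' @param phases Experimental [phase_dist] aligned with `refl`.
#' @param options A [dm_options()] list.
#' @return A data frame of class `dm_trace` with one row per cycle
#'   (`cycle, mean_fom, cpem, map_cc, d_mean, beta`), the initial-map
#'   correlation in attribute `initial_map_cc`, and the final state
#'   (combined phases, scaled model amplitudes/phases, covariance model) in
#'   attribute `final`.
#' @export
run_dm <- function(refl, phases, options = dm_options()) {
  stopifnot(inherits(refl, "refl_set"), inherits(phases, "phase_dist"),
            nrow(refl) == nrow(phases))
  opt <- options
  cell <- attr(refl, "cell")
  grid <- if (is.null(opt$grid)) default_grid(cell, min(refl$d)) else opt$grid
  hkl <- refl[, c("h", "k", "l")]
  binning <- assign_bins(refl, n_bins = opt$n_bins)
  refl$bin <- binning$bin

  exclude_free <- opt$use_free == "exclude_free"
  work <- if (exclude_free) !refl$free else rep(TRUE, nrow(refl))

  have_phases <- "phi_true" %in% names(refl)   # enough for CPEM
  have_truth <- "f_true" %in% names(refl)      # needed for the truth map
  truth_map <- NULL
  if (have_truth)
    truth_map <- synthesize_map(hkl, refl$f_true, cell, grid, label = "model")

  need_mask <- any(opt$ops %in% c("flatten", "histmatch"))
  target <- opt$target_histogram
  if ("histmatch" %in% opt$ops && is.null(target))
    target <- cached_default_histogram()

  comb <- phases
  cov <- NULL
  tr <- data.frame(cycle = seq_len(opt$n_cycles), mean_fom = NA_real_,
                   cpem = NA_real_, map_cc = NA_real_, d_mean = NA_real_,
                   beta = opt$beta)
  initial_cc <- NA_real_
  fc_amp <- NULL; fc_phi <- NULL

  for (cyc in seq_len(opt$n_cycles)) {
    coeffs <- if (cyc == 1) {
      comb$fom * refl$fo * exp(1i * comb$phi)
    } else {
      map_coefficients(comb, refl, cov, mode = opt$mode)
    }
    if (exclude_free) {
      # free reflections never see their observation or experimental phase:
      # zero on the first cycle, model-only (D_eff Fc) fill afterwards, the
      # standard missing-data treatment. The fill lets the real-space
      # constraints restore free amplitudes over cycles without coupling
      # the free observations into the procedure.
      coeffs[!work] <- if (cyc == 1) 0 else
        (cov$d_eff[refl$bin] * fc_amp * exp(1i * fc_phi))[!work]
    }
    map <- synthesize_map(hkl, coeffs, cell, grid, label = "combined")
    if (cyc == 1 && have_truth) initial_cc <- map_correlation(map, truth_map)

    mod <- map
    mask <- if (need_mask)
      wang_solvent_mask(mod, opt$solvent_fraction, opt$mask_radius)
    for (op in opt$ops) {
      mod <- switch(op,
                    null = null_modify(mod),
                    flatten = solvent_flatten(mod, mask),
                    histmatch = histogram_match(mod, mask, target))
    }

    fc <- map_to_structure_factors(mod, hkl)
    fc_amp <- Mod(fc); fc_phi <- Arg(fc)
    scl <- bin_scale(refl$fo, fc_amp, refl$bin, subset = work)
    fc_amp <- fc_amp * scl[refl$bin]

    luzz <- refine_luzzati(refl$fo, fc_amp, refl$bin, subset = work)
    cov <- apply_beta(luzz, opt$beta)
    comb <- combine_phases(phases, refl$fo, fc_amp, fc_phi, refl$bin, cov)
    attr(comb, "fc_amp") <- fc_amp

    tr$mean_fom[cyc] <- mean(comb$fom)
    tr$d_mean[cyc] <- mean(luzz$d)
    if (have_phases)
      tr$cpem[cyc] <- mean(cos(wrap_phase(comb$phi - refl$phi_true)))
    if (have_truth) {
      out_coeffs <- map_coefficients(comb, refl, cov, mode = opt$mode)
      out_coeffs[!work] <- 0
      tr$map_cc[cyc] <- map_correlation(
        synthesize_map(hkl, out_coeffs, cell, grid), truth_map)
    }
  }

  attr(tr, "initial_map_cc") <- initial_cc
  attr(tr, "final") <- list(comb = comb, fc_amp = fc_amp, fc_phi = fc_phi,
                            cov = cov, bin = refl$bin, work = work)
  attr(tr, "options") <- opt
  class(tr) <- c("dm_trace", "data.frame")
  tr
}

#' @export
print.dm_trace <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("dm_trace: %d cycles, final <m> = %.3f", n, x$mean_fom[n]))
  if (is.finite(x$cpem[n]))
    cat(sprintf(", CPEM = %.3f, map CC = %.3f", x$cpem[n], x$map_cc[n]))
  cat("\n")
  invisible(x)
}
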