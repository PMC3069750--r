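#' Select a cross-validation free set of reflections
#'
#' Random scheme: an exact-count random sample of the requested fraction
#' (without replacement), so the realised fraction matches the request to
#' within one reflection. Thin-shell scheme: reflections are ordered in
#' 1/d^2 and grouped into contiguous shells of `shell_size` reflections;
#' evenly spaced whole shells are flagged free until the fraction is
#' reached, so every shell is entirely free or entirely working.
#'
#' @param refl Reflection set.
#' @param fraction Free fraction, in (0, 0.5); 0.05 is the conventional
#'   choice.
#' @param scheme "random" or "thin_shells".
#' @param seed Integer seed (used by both schemes; thin shells randomize the
#'   starting shell).
#' @param shell_size Reflections per shell for the thin-shell scheme.
#' @return Logical vector of free flags with attributes `scheme`, `fraction`
#'   and `seed`.
#' @export
select_free_set <- function(refl, fraction = 0.05,
                            scheme = c("random", "thin_shells"), seed = 42,
                            shell_size = 20) {
  scheme <- match.arg(scheme)
  if (fraction <= 0 || fraction >= 0.5)
    stop("free fraction must lie in (0, 0.5)")
  n <- nrow(refl)
  n_free <- max(1L, round(fraction * n))
  if (n_free < 100)
    warning("free set has only ", n_free,
            " reflections; beta estimates will be noisy")
  set.seed(seed)
  flags <- logical(n)
  if (scheme == "random") {
    flags[sample.int(n, n_free)] <- TRUE
  } else {
    ord <- order(1 / refl$d^2, refl$h, refl$k, refl$l)
    shell <- integer(n)
    shell[ord] <- (seq_len(n) - 1L) %/% shell_size + 1L
    n_shells <- max(shell)
    need <- max(1L, round(fraction * n_shells))
    step <- n_shells / need
    start <- stats::runif(1, 0, step)
    picked <- unique(pmin(n_shells, floor(start + step * (seq_len(need) - 1)) + 1L))
    flags <- shell %in% picked
  }
  structure(flags, scheme = scheme, fraction = fraction, seed = seed)
}

# pooled within-bin mean-centred cross moment between fo and fc over `sel`,
# with fc brought onto the fo second moment per (bin, selection) first.
# The per-set scaling matters: model amplitudes for reflections excluded
# from map synthesis are systematically small, and without it the free-set
# cross moment would be attenuated by that scale rather than measure the
# free-set correlation the beta ratio is defined on.
pooled_covariance <- function(fo, fc, bin, sel) {
  tot <- 0
  den <- 0
  if (sum(sel) < 2) return(NA_real_)
  for (b in unique(bin[sel])) {
    s <- sel & bin == b
    n_b <- sum(s)
    if (n_b < 2) next
    m2c <- mean(fc[s]^2)
    scl <- if (m2c > 0) sqrt(mean(fo[s]^2) / m2c) else 0
    fcs <- fc[s] * scl
    tot <- tot + sum((fo[s] - mean(fo[s])) * (fcs - mean(fcs)))
    den <- den + n_b - 1      # unbiased pooled normalization
  }
  if (den < 1) return(NA_real_)
  tot / den
}

#' Cross-validated amplitude covariance ratio
#'
#' The core beta statistic: the ratio of the free-set to working-set
#' covariance between observed and model amplitudes. Within each resolution
#' bin and each set the model amplitudes are first scaled onto the observed
#' second moment, then the mean-centred cross moments are pooled across
#' bins; the ratio thus compares the free- and working-set correlation
#' structure rather than raw amplitude scales. A model
#' genuinely independent of the observations gives a ratio near one; a model
#' leaking observed amplitudes into its own gives a working-set covariance
#' that is artificially inflated, hence a ratio below one.
#'
#' @param fo Observed amplitudes.
#' @param fc Model amplitudes (any global positive scale; the ratio is
#'   invariant).
#' @param bin Resolution-bin ids.
#' @param free Logical free flags.
#' @return List with `beta` (ratio clamped to a tiny positive floor so
#'   downstream likelihoods stay defined), `raw_ratio`, `cov_free`,
#'   `cov_work`, `n_free`, `n_work`.
#' @export
covariance_ratio <- function(fo, fc, bin, free) {
  cov_free <- pooled_covariance(fo, fc, bin, free)
  cov_work <- pooled_covariance(fo, fc, bin, !free)
  if (!is.finite(cov_work) || cov_work <= 0)
    stop("working-set covariance is not positive; beta estimation failed")
  raw <- cov_free / cov_work
  list(beta = max(raw, 1e-6), raw_ratio = raw,
       cov_free = cov_free, cov_work = cov_work,
       n_free = sum(free), n_work = sum(!free))
}

#' Estimate the beta correction factor by cross-validation
#'
#' Runs `n_cycles` of density modification with the free reflections
#' completely excluded (zero map coefficient, no part in D refinement or
#' amplitude scaling), then computes the free/working covariance ratio
#' between observed and final-cycle model amplitudes. Because the free
#' reflections never feed the model, their covariance with it measures the
#' genuine information content of the modified map, while the working-set
#' covariance additionally contains the artificial component the beta
#' correction is meant to remove.
#'
#' @param refl Reflection set.
#' @param phases Experimental [phase_dist].
#' @param flags Logical free flags (see [select_free_set()]).
#' @param options A [dm_options()]; its `beta` and `use_free` fields are
#'   overridden for the estimation run.
#' @param n_cycles Estimation cycles (default 5).
#' @return Object of class `beta_estimate`: the [covariance_ratio()] fields
#'   plus `n_estimation_cycles` and the estimation trace in attribute
#'   `trace`.
#' @export
estimate_beta <- function(refl, phases, flags, options = dm_options(),
                          n_cycles = options$est_cycles) {
  stopifnot(length(flags) == nrow(refl))
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  refl$free <- as.logical(flags)
  opt <- options
  opt$n_cycles <- as.integer(n_cycles)
  opt$beta <- 1
  opt$use_free <- "exclude_free"
  tr <- run_dm(refl, phases, opt)
  fin <- attr(tr, "final")
  est <- covariance_ratio(refl$fo, fin$fc_amp, fin$bin, refl$free)
  est$n_estimation_cycles <- as.integer(n_cycles)
  attr(est, "trace") <- tr
  class(est) <- "beta_estimate"
  est
}

#' @export
print.beta_estimate <- function(x, ...) {
  cat(sprintf("beta = %.4f (cov_free = %.4g / cov_work = %.4g; %d free, %d work, %d cycles)\n",
              x$beta, x$cov_free, x$cov_work, x$n_free, x$n_work,
              x$n_estimation_cycles))
  invisible(x)
}

#' Two-stage beta-corrected density modification
#'
#' Stage 1 estimates beta: a free set is selected (unless the reflection set
#' already carries flags or `flags` is supplied), `est_cycles` cycles of
#' density modification are run on the working set alone, and beta is taken
#' as the free/working covariance ratio. Stage 2 restarts from the initial
#' experimental map and runs the production cycles using all reflections,
#' with beta held fixed at its estimate and applied after the per-cycle
#' Luzzati-D refinement. Supplying a numeric `beta` skips stage 1 entirely;
#' `beta = 1` therefore reproduces the uncorrected pipeline exactly.
#'
#' @param refl Reflection set.
#' @param phases Experimental [phase_dist].
#' @param options A [dm_options()] (production `n_cycles`, `est_cycles`,
#'   free-set parameters, operators, coefficient mode).
#' @param flags Optional explicit free flags for stage 1.
#' @param beta Optional fixed beta overriding estimation.
#' @return A `dm_trace` for the production run, with the stage-1
#'   [estimate_beta()] result (or NULL) in attribute `beta_estimate`.
#' @export
run_beta_corrected_dm <- function(refl, phases, options = dm_options(),
                                  flags = NULL, beta = NULL) {
  est <- NULL
  if (is.null(beta)) {
    if (is.null(flags)) {
      flags <- if (any(refl$free)) refl$free
      else select_free_set(refl, options$free_fraction,
                           options$free_scheme, options$free_seed)
    }
    est <- estimate_beta(refl, phases, flags, options)
    beta <- est$beta
  }
  opt <- options
  opt$beta <- beta
  opt$use_free <- "use_all"
  tr <- run_dm(refl, phases, opt)
  tr$beta <- beta
  attr(tr, "beta_estimate") <- est
  tr
}
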