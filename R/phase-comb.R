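#' Equal-count resolution bins in 1/d^2
#'
#' Assigns every reflection to a resolution bin with (near) equal counts in
#' increasing 1/d^2. Bins are merged until each holds at least 50
#' reflections, with a warning when the requested count cannot be honoured.
#'
#' @param refl Reflection set (needs column `d`).
#' @param n_bins Requested number of bins; NULL picks
#'   `max(1, min(12, floor(n/150)))`.
#' @return List with `bin` (integer id per reflection), `n_bins`, per-bin
#'   `counts` and bin-mean `d`.
#' @export
assign_bins <- function(refl, n_bins = NULL) {
  n <- nrow(refl)
  if (is.null(n_bins)) n_bins <- max(1L, min(12L, n %/% 150L))
  if (n_bins < 1) stop("n_bins must be >= 1")
  max_bins <- max(1L, n %/% 50L)
  if (n_bins > max_bins) {
    warning("fewer than 50 reflections per bin; merging to ", max_bins, " bins")
    n_bins <- max_bins
  }
  s2 <- 1 / refl$d^2
  ord <- order(s2, refl$h, refl$k, refl$l)   # stable, deterministic
  edges <- floor(seq(0, n, length.out = n_bins + 1))
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = diff(edges))
  list(bin = bin, n_bins = as.integer(n_bins),
       counts = tabulate(bin, n_bins),
       d_mean = vapply(split(refl$d, bin), mean, numeric(1), USE.NAMES = FALSE))
}

# per-bin scale carrying |Fc| onto the |Fo| second moment:
# s_b = sqrt(<Fo^2>_b / <Fc^2>_b), estimated on `subset` (working set).
# The cross-moment regression scale would absorb the Luzzati D itself, so
# moment matching is used instead and D keeps its meaning of a correlation.
bin_scale <- function(fo, fc, bin, subset = NULL) {
  if (is.null(subset)) subset <- rep(TRUE, length(fo))
  nb <- max(bin)
  s <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- subset & bin == b
    if (!any(sel)) sel <- bin == b
    denom <- mean(fc[sel]^2)
    s[b] <- if (denom > 0) sqrt(mean(fo[sel]^2) / denom) else 1
  }
  s
}

# log I0 without overflow; asymptotic expansion where the scaled Bessel
# underflows (x - log sqrt(2 pi x) is exact to ~1e-10 relative by x = 1e4)
log_bessel_i0 <- function(x) {
  out <- numeric(length(x))
  big <- x > 1e4
  if (any(big)) out[big] <- x[big] - 0.5 * log(2 * pi * x[big])
  if (any(!big))
    out[!big] <- log(besselI(x[!big], 0, expon.scaled = TRUE)) + x[!big]
  out
}

# acentric Rice log-likelihood of fo given model amplitude d*fc and
# residual variance s2
rice_loglik <- function(fo, fc, d, s2) {
  x <- 2 * fo * d * fc / s2
  sum(log(2 * fo / s2) - (fo^2 + d^2 * fc^2) / s2 + log_bessel_i0(x))
}

#' Per-bin Luzzati D refinement by the acentric Rice likelihood
#'
#' For each resolution bin, maximizes the acentric Rice likelihood of the
#' observed amplitudes given scaled model amplitudes over the Luzzati error
#' parameter D (bounded to [0, 1.2]) and the residual variance sigmaDelta^2,
#' via bounded quasi-Newton optimization from moment estimates. Ties on the
#' likelihood ridge are broken toward smaller D by a vanishing penalty.
#'
#' @param fo Observed amplitudes.
#' @param fc Model amplitudes on the observed scale (see internal per-bin
#'   scaling in [run_dm()]).
#' @param bin Integer bin ids from [assign_bins()].
#' @param subset Logical: reflections entering the refinement (e.g. the
#'   working set); the fitted model still applies to all.
#' @return Object of class `luzzati_model`: data frame with per-bin `d`,
#'   `sigma2` (residual variance), `mean_fc2` and `n`.
#' @export
refine_luzzati <- function(fo, fc, bin, subset = NULL) {
  if (is.null(subset)) subset <- rep(TRUE, length(fo))
  nb <- max(bin)
  out <- data.frame(bin = seq_len(nb), d = NA_real_, sigma2 = NA_real_,
                    mean_fc2 = NA_real_, n = NA_integer_)
  for (b in seq_len(nb)) {
    sel <- subset & bin == b
    if (!any(sel)) sel <- bin == b
    fob <- fo[sel]; fcb <- fc[sel]
    m2o <- mean(fob^2); m2c <- mean(fcb^2)
    out$mean_fc2[b] <- mean(fc[bin == b]^2)
    out$n[b] <- sum(sel)
    s2_floor <- 1e-6 * m2o
    d0 <- min(max(sum(fob * fcb) / sum(fcb^2), 0.01), 1.19)
    s20 <- max(m2o - d0^2 * m2c, 2 * s2_floor)
    obj <- function(p) {
      v <- -rice_loglik(fob, fcb, p[1], exp(p[2])) + 1e-7 * p[1]
      if (!is.finite(v)) v <- 1e300  # bounded surrogate keeps L-BFGS-B alive
      v
    }
    fit <- stats::optim(c(d0, log(s20)), obj, method = "L-BFGS-B",
                        lower = c(0, log(s2_floor)),
                        upper = c(1.2, log(10 * m2o + s2_floor)),
                        control = list(factr = 1e4, pgtol = 1e-8,
                                       maxit = 500))
    if (!fit$convergence %in% c(0L, 52L))
      stop("Luzzati refinement failed to converge in bin ", b,
           " (code ", fit$convergence, ")")
    out$d[b] <- fit$par[1]
    out$sigma2[b] <- exp(fit$par[2])
  }
  class(out) <- c("luzzati_model", "data.frame")
  out
}

#' Scale the model covariance by the beta correction factor
#'
#' Produces the effective covariance model used for phase combination:
#' D_eff = beta * D per bin, with the residual variance recomputed so the
#' per-bin second moment of the observations is preserved
#' (sigma2_eff = sigma2 + (1 - beta^2) D^2 <Fc^2>). beta = 1 reproduces the
#' uncorrected model exactly; beta < 1 expresses that part of the apparent
#' observed/model covariance is an artefact of deriving the model from the
#' observations.
#'
#' @param model A [refine_luzzati()] result.
#' @param beta Positive scalar.
#' @return Object of class `covariance_model`: the input per-bin table with
#'   `d_eff` and `sigma2_eff` columns and the beta value attached.
#' @export
apply_beta <- function(model, beta) {
  stopifnot(inherits(model, "luzzati_model"))
  if (!is.numeric(beta) || length(beta) != 1 || beta <= 0)
    stop("beta must be a positive scalar")
  out <- as.data.frame(model)
  out$d_eff <- beta * out$d
  out$sigma2_eff <- pmax(out$sigma2 + (1 - beta^2) * out$d^2 * out$mean_fc2,
                         1e-12 * (out$sigma2 + out$mean_fc2))
  attr(out, "beta") <- beta
  class(out) <- c("covariance_model", "data.frame")
  out
}

# centroid phase and figure of merit of exp(A cos + B sin + C cos2 + D sin2)
# by rectangle-rule quadrature on a uniform phase grid (spectrally accurate
# for smooth periodic integrands)
hl_centroid <- function(hla, hlb, hlc, hld, n_grid = 360) {
  phi <- seq(-pi, pi, length.out = n_grid + 1)[seq_len(n_grid)]
  basis <- rbind(cos(phi), sin(phi), cos(2 * phi), sin(2 * phi))
  lp <- cbind(hla, hlb, hlc, hld) %*% basis
  lp <- lp - apply(lp, 1, max)
  w <- exp(lp)
  z <- rowSums(w)
  cphi <- as.vector(w %*% cos(phi)) / z
  sphi <- as.vector(w %*% sin(phi)) / z
  list(phi = atan2(sphi, cphi), fom = pmin(sqrt(cphi^2 + sphi^2), 1))
}

#' Maximum-likelihood combination of experimental and model phases
#'
#' Adds the acentric Rice model phase kernel X cos(phi - phi_c), with
#' X = 2 D_eff |Fo| |Fc| / sigma2_eff taken per resolution bin, to the
#' experimental Hendrickson-Lattman log-density. The combined coefficients
#' are HL_exp + (X cos(phi_c), X sin(phi_c), 0, 0); centroid phase and
#' figure of merit are evaluated by 360-point quadrature over the phase
#' circle.
#'
#' @param exp_phases Experimental [phase_dist].
#' @param fo Observed amplitudes.
#' @param fc_amp Model amplitudes on the observed scale.
#' @param fc_phi Model phases in radians.
#' @param bin Integer resolution-bin ids.
#' @param cov A [apply_beta()] covariance model.
#' @return Combined [phase_dist] with updated HL coefficients, centroid
#'   phases and figures of merit.
#' @export
combine_phases <- function(exp_phases, fo, fc_amp, fc_phi, bin, cov) {
  stopifnot(inherits(exp_phases, "phase_dist"),
            inherits(cov, "covariance_model"))
  need <- c("hla", "hlb", "hlc", "hld")
  if (!all(need %in% names(exp_phases)))
    stop("experimental phase distribution lacks HL coefficients")
  x <- 2 * cov$d_eff[bin] * fo * fc_amp / cov$sigma2_eff[bin]
  if (any(!is.finite(x)))
    stop("non-finite model phase weight X at reflection ",
         which(!is.finite(x))[1])
  out <- exp_phases
  out$hla <- exp_phases$hla + x * cos(fc_phi)
  out$hlb <- exp_phases$hlb + x * sin(fc_phi)
  cen <- hl_centroid(out$hla, out$hlb, out$hlc, out$hld)
  out$phi <- cen$phi
  out$fom <- cen$fom
  out
}

#' Map coefficients from a combined phase distribution
#'
#' Centroid mode gives m |Fo| exp(i phi); 2mFo-DFc mode gives
#' (2 m |Fo| - D_eff |Fc|) exp(i phi) with the per-bin effective D, the
#' standard model-bias-suppressing synthesis for the next-cycle map.
#'
#' @param comb Combined [phase_dist].
#' @param refl Reflection set (amplitudes `fo`, bin ids `bin`, model
#'   amplitudes via `fc_amp`).
#' @param cov A [apply_beta()] covariance model (required for 2mFo-DFc).
#' @param mode "centroid" or "2mfodfc".
#' @param fc_amp Model amplitudes on the observed scale; defaults to the
#'   amplitudes the combination step attached to `comb`.
#' @return Complex coefficient vector aligned with `refl`.
#' @export
map_coefficients <- function(comb, refl, cov, mode = c("2mfodfc", "centroid"),
                             fc_amp = attr(comb, "fc_amp")) {
  mode <- match.arg(mode)
  amp <- comb$fom * refl$fo
  if (mode == "2mfodfc") {
    if (is.null(fc_amp)) stop("2mFo-DFc coefficients require model amplitudes")
    amp <- 2 * comb$fom * refl$fo - cov$d_eff[refl$bin] * fc_amp
  }
  amp * exp(1i * comb$phi)
}
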