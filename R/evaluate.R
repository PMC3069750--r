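#' Phase-error statistics against ground truth
#'
#' @param comb A [phase_dist] (or anything with a `phi` column).
#' @param phi_true True phases in radians, same length.
#' @return List with `cpem` (mean cosine of the phase error) and
#'   `mean_abs_error` (mean |delta phi| in radians, errors wrapped to
#'   (-pi, pi]).
#' @export
phase_error_stats <- function(comb, phi_true) {
  phi <- if (is.data.frame(comb)) comb$phi else comb
  if (length(phi) != length(phi_true))
    stop("phase vectors differ in length")
  d <- wrap_phase(phi - phi_true)
  list(cpem = mean(cos(d)), mean_abs_error = mean(abs(d)))
}

#' Average statistical bias of figure-of-merit estimates
#'
#' Mean over data sets of (mean FOM - CPEM): positive values mean the
#' procedure claims better phases than it delivered.
#'
#' @param reports Data frame with columns `mean_fom` and `cpem`, one row per
#'   data set (see [run_bias_experiment()]), or a list of such rows.
#' @return Scalar bias.
#' @export
statistical_bias <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) < 1) stop("at least one report is required")
  mean(reports$mean_fom - reports$cpem)
}

#' Figure of merit corrected for bias inherited from phasing
#'
#' m_corr = m_dm - (m_ph - cpem_ph): subtracts the statistical bias already
#' present after experimental phasing, isolating the bias added by density
#' modification itself.
#'
#' @param m_dm Mean FOM after density modification.
#' @param m_ph Mean FOM after experimental phasing.
#' @param cpem_ph Mean cosine of the phase error after phasing.
#' @return Corrected figure of merit (may leave [0,1] when the phasing bias
#'   exceeds the DM gain).
#' @export
phasing_corrected_fom <- function(m_dm, m_ph, cpem_ph) {
  m_dm - (m_ph - cpem_ph)
}

#' Nadaraya-Watson kernel regression of CPEM on FOM
#'
#' Gaussian-kernel weighted mean of `cpem` as a function of `fom`, with
#' optional leave-one-out evaluation at the design points (each data set's
#' estimate uses every data set but itself). Bandwidth defaults to
#' Silverman's rule on the FOM values.
#'
#' @param fom Per-data-set mean figures of merit.
#' @param cpem Per-data-set mean cosines of the phase error.
#' @param bandwidth Gaussian kernel bandwidth; NULL = Silverman.
#' @param loo Leave-one-out at the design points (default TRUE).
#' @param grid Optional query grid; defaults to the design points.
#' @return Object of class `calibration_curve`: list with `grid`,
#'   `estimate`, `bandwidth`, `residuals` (loo residuals at the design
#'   points when `loo`), and `rms` of those residuals. Queries where every
#'   kernel weight underflows yield NA rather than an extrapolated value.
#' @export
nadaraya_watson <- function(fom, cpem, bandwidth = NULL, loo = TRUE,
                            grid = NULL) {
  n <- length(fom)
  if (n < 3) stop("kernel regression needs at least 3 data sets")
  if (length(cpem) != n) stop("fom and cpem differ in length")
  if (is.null(bandwidth)) bandwidth <- 1.06 * stats::sd(fom) * n^(-1/5)
  if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 0.05
  est_at <- function(x, exclude = 0L) {
    w <- stats::dnorm(fom - x, sd = bandwidth)
    if (exclude > 0L) w[exclude] <- 0
    tw <- sum(w)
    if (tw <= 0 || !is.finite(tw)) return(NA_real_)
    sum(w * cpem) / tw
  }
  residuals <- rms <- NULL
  if (loo) {
    pred <- vapply(seq_len(n), function(i) est_at(fom[i], i), numeric(1))
    residuals <- cpem - pred
    rms <- sqrt(mean(residuals^2, na.rm = TRUE))
  }
  if (is.null(grid)) grid <- fom
  estimate <- vapply(grid, est_at, numeric(1))
  structure(list(grid = grid, estimate = estimate, bandwidth = bandwidth,
                 residuals = residuals, rms = rms),
            class = "calibration_curve")
}

#' RMS errors of CPEM estimation by FOM
#'
#' Two estimators of a data set's true phase quality (CPEM): the mean FOM
#' itself (direct), and the leave-one-out kernel-regression prediction from
#' the other data sets' (FOM, CPEM) pairs.
#'
#' @param reports Data frame with `mean_fom` and `cpem` columns.
#' @param bandwidth Optional kernel bandwidth for the regression branch.
#' @return List with `rms_direct` and `rms_regression`.
#' @export
estimator_error <- function(reports, bandwidth = NULL) {
  reports <- as.data.frame(reports)
  if (nrow(reports) < 3) stop("need at least 3 reports")
  nw <- nadaraya_watson(reports$mean_fom, reports$cpem,
                        bandwidth = bandwidth, loo = TRUE)
  list(rms_direct = sqrt(mean((reports$mean_fom - reports$cpem)^2)),
       rms_regression = nw$rms)
}
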