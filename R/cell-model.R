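#' Orthogonal P1 unit cell
#'
#' Constructs a unit-cell description. Only orthogonal cells (all angles 90
#' degrees) in space group P1 are supported: this keeps every reflection
#' acentric and avoids symmetry bookkeeping, which is all the toy crystals
#' here require.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; fixed at 90.
#' @return An object of class `unit_cell` with fields `a`, `b`, `c`, the
#'   three angles, `spacegroup` (always `"P1"`) and `volume` in cubic
#'   Angstrom.
#' @examples
#' unit_cell(20, 22, 24)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (!all(is.finite(c(a, b, c))) || any(c(a, b, c) <= 0))
    stop("cell lengths must be positive and finite")
  if (any(c(alpha, beta, gamma) != 90))
    stop("only orthogonal cells (90 degree angles) are supported")
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         spacegroup = "P1", volume = a * b * c),
    class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("P1 cell %.2f x %.2f x %.2f A (V = %.0f A^3)\n",
              x$a, x$b, x$c, x$volume))
  invisible(x)
}

#' Random point-atom model in a P1 cell
#'
#' Places `n_atoms` point scatterers uniformly in the unit cell. Each atom
#' carries a scattering weight drawn from a small fixed palette (roughly the
#' electron counts of C, N, O and S), an isotropic B factor drawn uniformly
#' from `b_range`, and unit occupancy. The Gaussian B-factor falloff of a
#' point atom is enough to give the amplitude statistics of a protein-sized
#' scatterer set without tabulated form factors.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param cell A [unit_cell()].
#' @param b_range Length-2 numeric, B-factor interval in square Angstrom.
#' @param seed Integer seed; the model is a pure function of the arguments
#'   and the seed.
#' @return An object of class `atom_model`: list with `xyz` (n x 3 matrix of
#'   fractional coordinates in `[0,1)`), `b`, `occ`, `weight` and `cell`.
#' @export
generate_toy_structure <- function(n_atoms, cell, b_range = c(10, 30), seed = 1) {
  if (!is.numeric(n_atoms) || length(n_atoms) != 1 || n_atoms < 1)
    stop("n_atoms must be a positive count")
  stopifnot(inherits(cell, "unit_cell"), length(b_range) == 2)
  n_atoms <- as.integer(n_atoms)
  set.seed(seed)
  xyz <- matrix(stats::runif(3 * n_atoms), ncol = 3)
  xyz <- xyz %% 1
  colnames(xyz) <- c("x", "y", "z")
  palette <- c(6, 7, 8, 16)  # C, N, O, S electron counts
  structure(
    list(xyz = xyz,
         b = stats::runif(n_atoms, b_range[1], b_range[2]),
         occ = rep(1, n_atoms),
         weight = sample(palette, n_atoms, replace = TRUE,
                         prob = c(0.55, 0.2, 0.2, 0.05)),
         cell = cell),
    class = "atom_model")
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("atom_model: %d atoms, <B> = %.1f A^2, total weight %.0f\n",
              nrow(x$xyz), mean(x$b), sum(x$weight * x$occ)))
  invisible(x)
}

# 1/d^2 for an orthogonal cell
inv_d2 <- function(h, k, l, cell) {
  (h / cell$a)^2 + (k / cell$b)^2 + (l / cell$c)^2
}

#' Unique-hemisphere Miller indices to a resolution limit
#'
#' Enumerates all Miller indices with d >= `d_min`, excluding (0,0,0) and
#' keeping a single Friedel hemisphere (l > 0, or l = 0 and k > 0, or
#' k = l = 0 and h > 0). In P1 the Friedel mate carries no independent
#' information for real scatterers, so one hemisphere is the complete
#' unique set.
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom (> 0).
#' @return Data frame with integer columns `h`, `k`, `l` and numeric `d`,
#'   sorted by decreasing resolution spacing d.
#' @export
hkl_hemisphere <- function(cell, d_min) {
  stopifnot(d_min > 0)
  hmax <- floor(cell$a / d_min)
  kmax <- floor(cell$b / d_min)
  lmax <- floor(cell$c / d_min)
  g <- expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = 0:lmax)
  s2 <- inv_d2(g$h, g$k, g$l, cell)
  hemi <- g$l > 0 | (g$l == 0 & g$k > 0) | (g$l == 0 & g$k == 0 & g$h > 0)
  keep <- hemi & s2 <= 1 / d_min^2 & s2 > 0
  g <- g[keep, , drop = FALSE]
  s2 <- s2[keep]
  ord <- order(s2, g$h, g$k, g$l)
  out <- data.frame(h = as.integer(g$h[ord]), k = as.integer(g$k[ord]),
                    l = as.integer(g$l[ord]), d = 1 / sqrt(s2[ord]))
  rownames(out) <- NULL
  out
}

#' Direct-summation structure factors at arbitrary Miller indices
#'
#' Computes F(h) = sum_j w_j occ_j exp(-B_j s^2 / 4) exp(2 pi i h.x_j) with
#' s = 1/d by explicit summation over atoms. This is the slow, exact path
#' used as the oracle for the FFT map transforms.
#'
#' @param model An [atom_model()].
#' @param hkl Data frame or matrix with columns h, k, l.
#' @return Complex vector of structure factors, one per row of `hkl`.
#' @export
structure_factors_at <- function(model, hkl) {
  stopifnot(inherits(model, "atom_model"))
  hkl <- as.matrix(as.data.frame(hkl)[, c("h", "k", "l")])
  s2 <- inv_d2(hkl[, 1], hkl[, 2], hkl[, 3], model$cell)
  # atoms x reflections phase matrix
  ph <- model$xyz %*% t(hkl)                       # h.x
  fall <- exp(-outer(model$b, s2) / 4)             # B-factor falloff
  w <- model$weight * model$occ
  colSums((w * fall) * exp(2i * pi * ph))
}

#' Full reflection set of a toy model by direct summation
#'
#' Builds the unique-hemisphere reflection list to `d_min` and fills in the
#' true complex structure factors of `model` by direct summation
#' ([structure_factors_at()]). Observed amplitudes are initialised to
#' |F_true| with a nominal sigma; add measurement noise afterwards with
#' [add_amplitude_noise()].
#'
#' @param model An [atom_model()].
#' @param d_min Resolution limit in Angstrom.
#' @return A reflection set: data frame of class `refl_set` with columns
#'   `h,k,l,d,fo,sigfo,f_true` (complex), `phi_true`, `free`, `bin` and the
#'   cell stored as attribute `cell`.
#' @export
direct_structure_factors <- function(model, d_min) {
  if (!inherits(model, "atom_model") || nrow(model$xyz) < 1)
    stop("model must be an atom_model with at least one atom")
  hkl <- hkl_hemisphere(model$cell, d_min)
  f <- structure_factors_at(model, hkl)
  refl <- data.frame(hkl, fo = Mod(f), sigfo = pmax(0.01 * Mod(f), 1e-6),
                     phi_true = Arg(f), free = FALSE, bin = 1L)
  refl$f_true <- f
  attr(refl, "cell") <- model$cell
  attr(refl, "d_min") <- d_min
  class(refl) <- c("refl_set", "data.frame")
  refl
}

#' @export
print.refl_set <- function(x, ...) {
  cat(sprintf("refl_set: %d unique reflections, %.2f-%.2f A%s\n",
              nrow(x), max(x$d), min(x$d),
              if ("f_true" %in% names(x)) " (ground truth present)" else ""))
  invisible(x)
}

# von Mises(0, kappa) sampler, Best & Fisher (1979) rejection scheme.
# kappa = 0 degenerates to the uniform distribution on (-pi, pi].
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    v <- sign(u3[acc] - 0.5) * acos(pmin(1, pmax(-1, f[acc])))
    k <- length(v)
    if (k > 0) out[(got + 1):(got + k)] <- v
    got <- got + k
  }
  out
}

# I1(kappa)/I0(kappa) = E[cos(delta)] for delta ~ von Mises(0, kappa);
# this is also the figure of merit of a von Mises phase distribution.
bessel_ratio <- function(kappa) {
  ifelse(kappa < 1e-12, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Simulate experimental phase information with known error statistics
#'
#' Emulates the output of an experimental phasing step. For each reflection a
#' phase error delta is drawn from a von Mises(0, kappa) distribution and the
#' reported centroid phase is set to the true phase plus delta. The
#' Hendrickson-Lattman coefficients are the exact von Mises ones,
#' A = kappa cos(phi), B = kappa sin(phi), C = D = 0, so the stored figure of
#' merit m = I1(kappa)/I0(kappa) is calibrated by construction: the expected
#' cosine of the simulated phase error equals m.
#'
#' An optional `kappa_reported` different from `kappa` miscalibrates the
#' distribution deliberately (HL coefficients and m claim `kappa_reported`
#' while the errors are drawn with `kappa`), mimicking overconfident
#' upstream phasing.
#'
#' @param refl Reflection set with `f_true` present.
#' @param kappa von Mises concentration of the true phase errors (>= 0).
#' @param seed Integer seed.
#' @param kappa_reported Concentration encoded in the HL coefficients;
#'   defaults to `kappa` (calibrated simulation).
#' @return A phase distribution: data frame of class `phase_dist` with
#'   columns `hla,hlb,hlc,hld`, centroid `phi` in (-pi, pi] and `fom`.
#' @export
simulate_experimental_phases <- function(refl, kappa, seed = 1,
                                         kappa_reported = kappa) {
  stopifnot(inherits(refl, "refl_set"))
  if (!"f_true" %in% names(refl)) stop("refl must carry true structure factors")
  if (!is.numeric(kappa) || kappa < 0) stop("kappa must be >= 0")
  if (kappa_reported < 0) stop("kappa_reported must be >= 0")
  set.seed(seed)
  delta <- rvonmises(nrow(refl), kappa)
  phi <- wrap_phase(refl$phi_true + delta)
  out <- data.frame(hla = kappa_reported * cos(phi),
                    hlb = kappa_reported * sin(phi),
                    hlc = 0, hld = 0,
                    phi = phi,
                    fom = rep(bessel_ratio(kappa_reported), nrow(refl)))
  class(out) <- c("phase_dist", "data.frame")
  out
}

#' @export
print.phase_dist <- function(x, ...) {
  cat(sprintf("phase_dist: %d reflections, <m> = %.3f\n", nrow(x), mean(x$fom)))
  invisible(x)
}

#' Add multiplicative measurement noise to observed amplitudes
#'
#' Sets |Fo| = |F_true| (1 + eps) with eps ~ Normal(0, relative_sigma),
#' truncated below at -0.99 so amplitudes stay positive, and records the
#' implied sigma.
#'
#' @param refl Reflection set with `f_true`.
#' @param relative_sigma Relative noise level (>= 0); 0 returns exact
#'   amplitudes.
#' @param seed Integer seed.
#' @return The reflection set with updated `fo` and `sigfo`.
#' @export
add_amplitude_noise <- function(refl, relative_sigma, seed = 1) {
  stopifnot(inherits(refl, "refl_set"))
  if (!is.numeric(relative_sigma) || relative_sigma < 0)
    stop("relative_sigma must be >= 0")
  ftrue <- Mod(refl$f_true)
  if (relative_sigma == 0) {
    refl$fo <- ftrue
  } else {
    set.seed(seed)
    eps <- pmax(stats::rnorm(nrow(refl), 0, relative_sigma), -0.99)
    refl$fo <- ftrue * (1 + eps)
  }
  refl$sigfo <- pmax(relative_sigma * ftrue, 1e-6)
  refl
}

# wrap angles into (-pi, pi]
wrap_phase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
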