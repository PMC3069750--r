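#' Real-space density map over a P1 cell
#'
#' Thin container for a density grid. Values are stored in an
#' `nx x ny x nz` array with x fastest (R's native array order); grid point
#' `[i,j,k]` samples fractional position ((i-1)/nx, (j-1)/ny, (k-1)/nz).
#'
#' @param rho Numeric 3-d array of density samples; all values finite.
#' @param cell A [unit_cell()].
#' @param label Provenance label, one of "experimental", "modified",
#'   "combined", "model".
#' @return Object of class `density_map`.
#' @export
density_map <- function(rho, cell, label = "experimental") {
  stopifnot(is.array(rho), length(dim(rho)) == 3, inherits(cell, "unit_cell"))
  if (!all(is.finite(rho))) stop("density values must be finite")
  structure(list(rho = rho, cell = cell, label = label), class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$rho)
  cat(sprintf("density_map [%s]: %d x %d x %d grid, sd = %.3g\n",
              x$label, d[1], d[2], d[3], stats::sd(x$rho)))
  invisible(x)
}

#' Default map grid for a resolution limit
#'
#' Chooses FFT-friendly grid dimensions with spacing at most `d_min/3` along
#' every cell axis (three grid points per minimum d-spacing, common
#' crystallographic sampling).
#'
#' @param cell A [unit_cell()].
#' @param d_min Resolution limit in Angstrom.
#' @return Integer vector (nx, ny, nz).
#' @export
default_grid <- function(cell, d_min) {
  n <- vapply(c(cell$a, cell$b, cell$c),
              function(len) stats::nextn(ceiling(3 * len / d_min), c(2, 3, 5)),
              integer(1))
  pmax(n, 8L)
}

# linear (1-based) position of Miller index h in an n-point FFT axis
fft_index <- function(h, n) (h %% n) + 1L

#' Fourier synthesis of a density map from reflection coefficients
#'
#' Computes rho(x) = sum over the stored hemisphere of Re(F(h)
#' exp(-2 pi i h.x)) on the grid, i.e. each unique reflection together with
#' its implied Friedel mate contributes |F| cos(2 pi h.x - phi). F(000) is
#' always treated as zero, so maps are mean-zero by construction.
#'
#' @param hkl Data frame with columns h, k, l (one hemisphere, no (0,0,0)).
#' @param coeffs Complex coefficient vector, one per row of `hkl`.
#' @param cell A [unit_cell()].
#' @param grid Integer vector (nx, ny, nz); every |h| must stay below the
#'   grid Nyquist limit, otherwise an error is raised.
#' @param label Provenance label for the resulting map.
#' @return A [density_map()].
#' @export
synthesize_map <- function(hkl, coeffs, cell, grid, label = "combined") {
  hkl <- as.data.frame(hkl)
  stopifnot(nrow(hkl) == length(coeffs), length(grid) == 3)
  grid <- as.integer(grid)
  hm <- c(max(abs(hkl$h)), max(abs(hkl$k)), max(abs(hkl$l)))
  if (any(hm >= (grid + 1) %/% 2) || any(2 * hm >= grid))
    stop("grid too coarse for the requested Miller indices (Nyquist violation)")
  g <- array(0 + 0i, grid)
  ip <- cbind(fft_index(hkl$h, grid[1]), fft_index(hkl$k, grid[2]),
              fft_index(hkl$l, grid[3]))
  im <- cbind(fft_index(-hkl$h, grid[1]), fft_index(-hkl$k, grid[2]),
              fft_index(-hkl$l, grid[3]))
  g[ip] <- coeffs / 2
  g[im] <- Conj(coeffs) / 2
  rho <- Re(stats::fft(g))
  density_map(rho, cell, label)
}

#' Fourier analysis of a map at requested Miller indices
#'
#' Inverse of [synthesize_map()]: F(h) = 2 <rho(x) exp(2 pi i h.x)>, the
#' average running over all grid points. On a band-limited map the pair
#' synthesize/invert is the identity to rounding error.
#'
#' @param map A [density_map()].
#' @param hkl Data frame with columns h, k, l; every index must be below the
#'   grid Nyquist limit.
#' @return Complex vector of structure-factor coefficients.
#' @export
map_to_structure_factors <- function(map, hkl) {
  stopifnot(inherits(map, "density_map"))
  hkl <- as.data.frame(hkl)
  grid <- dim(map$rho)
  hm <- c(max(abs(hkl$h)), max(abs(hkl$k)), max(abs(hkl$l)))
  if (any(hm >= (grid + 1) %/% 2) || any(2 * hm >= grid))
    stop("requested Miller index beyond the grid Nyquist limit")
  ft <- stats::fft(map$rho, inverse = TRUE)
  idx <- cbind(fft_index(hkl$h, grid[1]), fft_index(hkl$k, grid[2]),
               fft_index(hkl$l, grid[3]))
  2 * ft[idx] / prod(grid)
}

#' Pearson correlation between two density maps
#'
#' The map-quality measure used throughout: correlation over all grid points
#' of the full cell, invariant to affine rescaling of either map.
#'
#' @param a,b [density_map()]s on identical grids.
#' @return Correlation coefficient in [-1, 1].
#' @export
map_correlation <- function(a, b) {
  stopifnot(inherits(a, "density_map"), inherits(b, "density_map"))
  if (!identical(dim(a$rho), dim(b$rho)))
    stop("maps must share an identical grid")
  stats::cor(as.vector(a$rho), as.vector(b$rho))
}
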