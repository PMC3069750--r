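#' Write a reflection set and its phase information to a text file
#'
#' Columnar whitespace-separated format with header
#' `H K L D FO SIGFO HLA HLB HLC HLD PHITRUE FREE`; phases are written in
#' degrees. `PHITRUE` is NA when no ground truth is present (real data).
#'
#' @param refl Reflection set.
#' @param phases Matching [phase_dist].
#' @param file Output path.
#' @export
write_reflections <- function(refl, phases, file) {
  stopifnot(nrow(refl) == nrow(phases))
  out <- data.frame(H = refl$h, K = refl$k, L = refl$l,
                    D = round(refl$d, 5),
                    FO = signif(refl$fo, 8), SIGFO = signif(refl$sigfo, 8),
                    HLA = signif(phases$hla, 8), HLB = signif(phases$hlb, 8),
                    HLC = signif(phases$hlc, 8), HLD = signif(phases$hld, 8),
                    PHITRUE = if ("phi_true" %in% names(refl))
                      round(refl$phi_true * 180 / pi, 4) else NA,
                    FREE = as.integer(refl$free))
  utils::write.table(out, file, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a reflection file written by [write_reflections()]
#'
#' @param file Input path.
#' @param cell The [unit_cell()] the reflections belong to (the text format
#'   does not embed it).
#' @return List with `refl` (reflection set; `phi_true` only if present in
#'   the file) and `phases` (experimental phase distribution with centroid
#'   phase and FOM recomputed from the HL coefficients by quadrature).
#' @export
read_reflections <- function(file, cell) {
  stopifnot(inherits(cell, "unit_cell"))
  tab <- utils::read.table(file, header = TRUE)
  need <- c("H", "K", "L", "FO", "SIGFO", "HLA", "HLB", "HLC", "HLD")
  if (!all(need %in% names(tab)))
    stop("missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  d <- 1 / sqrt(inv_d2(tab$H, tab$K, tab$L, cell))
  refl <- data.frame(h = as.integer(tab$H), k = as.integer(tab$K),
                     l = as.integer(tab$L), d = d,
                     fo = tab$FO, sigfo = tab$SIGFO,
                     free = if ("FREE" %in% names(tab)) tab$FREE > 0 else FALSE,
                     bin = 1L)
  if ("PHITRUE" %in% names(tab) && !anyNA(tab$PHITRUE))
    refl$phi_true <- wrap_phase(tab$PHITRUE * pi / 180)
  attr(refl, "cell") <- cell
  class(refl) <- c("refl_set", "data.frame")
  cen <- hl_centroid(tab$HLA, tab$HLB, tab$HLC, tab$HLD)
  phases <- data.frame(hla = tab$HLA, hlb = tab$HLB, hlc = tab$HLC,
                       hld = tab$HLD, phi = cen$phi, fom = cen$fom)
  class(phases) <- c("phase_dist", "data.frame")
  list(refl = refl, phases = phases)
}

#' Write combined phases and map coefficients
#'
#' Output columns `H K L FOM PHICOMB HLA HLB HLC HLD FWT PHWT`, phases in
#' degrees, where FWT/PHWT are the amplitude and phase of the selected map
#' coefficients.
#'
#' @param refl Reflection set.
#' @param comb Combined [phase_dist].
#' @param coeffs Complex map coefficients aligned with `refl`.
#' @param file Output path.
#' @export
write_combined <- function(refl, comb, coeffs, file) {
  out <- data.frame(H = refl$h, K = refl$k, L = refl$l,
                    FOM = round(comb$fom, 6),
                    PHICOMB = round(comb$phi * 180 / pi, 4),
                    HLA = signif(comb$hla, 8), HLB = signif(comb$hlb, 8),
                    HLC = signif(comb$hlc, 8), HLD = signif(comb$hld, 8),
                    FWT = signif(Mod(coeffs), 8),
                    PHWT = round(Arg(coeffs) * 180 / pi, 4))
  utils::write.table(out, file, quote = FALSE, row.names = FALSE)
  invisible(file)
}
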