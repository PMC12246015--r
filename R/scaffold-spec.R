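#' Parametric strand-lattice scaffold design
#'
#' Describes a 0/90 strand-lattice scaffold deposited inside a cylindrical
#' envelope, as printed by direct ink writing (DIW): `N_V` horizontal layers
#' of `N_H` parallel strands each, alternating orientation by 90 degrees
#' between layers.
#'
#' Span conventions (used when `Y` or `h` are not given explicitly):
#' * horizontal centre-to-centre span `Y = D_scaffold / N_H`, i.e. the strand
#'   pattern tiles the envelope diameter with half a pore window at each rim;
#' * vertical centre-to-centre span `h = H_scaffold / N_V`, i.e. the layer
#'   stack tiles the scaffold height, with the outermost strand surfaces
#'   trimmed flush at the piston and support contact faces. Because
#'   `h < D_strand` whenever `N_V * D_strand > H_scaffold`, adjacent layers
#'   interpenetrate by `D_strand - h`, emulating strand fusion during
#'   printing.
#'
#' Designs are named `S{step}-H{N_H}-V{N_V}`.
#'
#' @param N_H number of strands per horizontal layer (>= 2).
#' @param N_V number of layers in the vertical direction (>= 1).
#' @param D_scaffold scaffold (envelope) diameter, mm.
#' @param H_scaffold scaffold height, mm.
#' @param D_strand strand diameter, mm.
#' @param Y horizontal centre-to-centre span, mm. Default `D_scaffold / N_H`.
#' @param h vertical centre-to-centre span, mm. Default `H_scaffold / N_V`.
#' @param step modification-step label used in the design name (0 denotes the
#'   original design).
#' @param name design label; derived from `step`, `N_H`, `N_V` when `NULL`.
#' @return An object of class `scaffold_spec`.
#' @examples
#' spec <- scaffold_spec(N_H = 7, N_V = 9, step = 0)
#' spec
#' pore_equivalent_diameter(spec)
#' @seealso [build_layout()], [pore_metrics()], [step1_designs()]
#' @export
scaffold_spec <- function(N_H, N_V, D_scaffold = 10, H_scaffold = 4.8,
                          D_strand = 0.7, Y = NULL, h = NULL,
                          step = NA_integer_, name = NULL) {
  stopifnot_scalar(N_H, "N_H", positive = TRUE, integer = TRUE)
  stopifnot_scalar(N_V, "N_V", positive = TRUE, integer = TRUE)
  stopifnot_scalar(D_scaffold, "D_scaffold", positive = TRUE)
  stopifnot_scalar(H_scaffold, "H_scaffold", positive = TRUE)
  stopifnot_scalar(D_strand, "D_strand", positive = TRUE)
  if (N_H < 2) stop("'N_H' must be at least 2", call. = FALSE)
  if (is.null(Y)) Y <- D_scaffold / N_H
  if (is.null(h)) h <- H_scaffold / N_V
  stopifnot_scalar(Y, "Y", positive = TRUE)
  stopifnot_scalar(h, "h", positive = TRUE)
  if (Y <= D_strand)
    stop("invalid geometry: Y <= D_strand leaves no open pore window",
         call. = FALSE)
  tol <- 1e-9
  if (N_V * h > H_scaffold + tol)
    stop("invalid geometry: layer stack N_V * h exceeds H_scaffold",
         call. = FALSE)
  if (N_V > 1 && N_V * D_strand > H_scaffold && h > D_strand + tol)
    stop("invalid geometry: h > D_strand with N_V * D_strand > H_scaffold ",
         "(layers neither fit nor interpenetrate)", call. = FALSE)
  if (N_V > 1 && h > D_strand + tol)
    warning("h > D_strand: layers do not touch; the lattice is disconnected")
  if (is.null(name))
    name <- sprintf("S%s-H%d-V%d",
                    if (is.na(step)) "x" else as.character(step), N_H, N_V)
  structure(
    list(name = name, D_scaffold = D_scaffold, H_scaffold = H_scaffold,
         D_strand = D_strand, N_H = as.integer(N_H), N_V = as.integer(N_V),
         Y = Y, h = h, step = step),
    class = "scaffold_spec")
}

#' The original reference scaffold design
#'
#' Convenience constructor for the S0-H7-V9 design: a 10 mm diameter,
#' 4.8 mm tall lattice of 700 um strands with 7 strands per layer and 9
#' layers.
#'
#' @return A [scaffold_spec()] object named `"S0-H7-V9"`.
#' @export
original_scaffold <- function() {
  scaffold_spec(N_H = 7, N_V = 9, step = 0)
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat(sprintf("Strand-lattice scaffold design '%s'\n", x$name))
  cat(sprintf("  envelope: D = %g mm, H = %g mm\n", x$D_scaffold, x$H_scaffold))
  cat(sprintf("  strands:  D_strand = %g um, N_H = %d, N_V = %d\n",
              1000 * x$D_strand, x$N_H, x$N_V))
  cat(sprintf("  spans:    Y = %.4g mm, h = %.4g mm\n", x$Y, x$h))
  dp <- tryCatch(pore_equivalent_diameter(x), error = function(e) NA_real_)
  if (is.finite(dp)) cat(sprintf("  D_pore:   %.0f um\n", dp))
  invisible(x)
}

is_scaffold_spec <- function(x) inherits(x, "scaffold_spec")

envelope_volume <- function(spec) {
  pi * (spec$D_scaffold / 2)^2 * spec$H_scaffold
}
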