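#' Build the concrete strand layout of a lattice design
#'
#' Expands a [scaffold_spec()] into the list of strand axes: `N_V` layers
#' alternating between 0 degrees (strand axes along x) and 90 degrees (axes
#' along y), each carrying `N_H` strands at centre-to-centre span `Y`
#' centred on the scaffold axis. Layer centre heights are `(i - 1/2) * h`,
#' so the stack tiles `[0, H_scaffold]` and the outermost strand surfaces
#' are trimmed flush at the contact faces. Strand axes are clipped to the
#' circular envelope; strands whose lateral offset reaches the envelope
#' radius produce zero-length chords and are excluded.
#'
#' @param spec a [scaffold_spec()].
#' @return A data frame of class `strand_layout` with one row per strand:
#'   `layer`, `orientation` (0 or 90), `offset` (lateral axis offset, mm),
#'   `z` (layer centre height, mm), `chord` (clipped axis length, mm) and
#'   the chord endpoints `x0, y0, x1, y1`. The generating `spec` is attached
#'   as an attribute.
#' @examples
#' nrow(build_layout(scaffold_spec(N_H = 7, N_V = 9)))  # 63 strands
#' @export
build_layout <- function(spec) {
  stopifnot(is_scaffold_spec(spec))
  R <- spec$D_scaffold / 2
  rows <- vector("list", spec$N_V)
  for (i in seq_len(spec$N_V)) {
    zc <- (i - 0.5) * spec$h
    ori <- if (i %% 2 == 1) 0 else 90
    offs <- (seq_len(spec$N_H) - (spec$N_H + 1) / 2) * spec$Y
    offs <- offs[abs(offs) < R]    # tangent/outside chords excluded
    if (length(offs) == 0) next
    half <- sqrt(R^2 - offs^2)
    rows[[i]] <- data.frame(
      layer = i, orientation = ori, offset = offs, z = zc, chord = 2 * half,
      x0 = if (ori == 0) -half else offs,
      y0 = if (ori == 0) offs else -half,
      x1 = if (ori == 0) half else offs,
      y1 = if (ori == 0) offs else half)
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("invalid geometry: no strand lies inside the cylindrical envelope",
         call. = FALSE)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  class(out) <- c("strand_layout", "data.frame")
  out
}

layout_spec <- function(layout) attr(layout, "spec")

#' @export
print.strand_layout <- function(x, ...) {
  spec <- layout_spec(x)
  cat(sprintf("Strand layout%s: %d strands in %d layers\n",
              if (!is.null(spec)) paste0(" of '", spec$name, "'") else "",
              nrow(x), length(unique(x$layer))))
  NextMethod()
}

# Crossing points between strands of adjacent (orthogonal) layers.
# Each crossing lies at the lateral offsets of the two strands, mid-height
# between the layer centres, and must fall inside the envelope circle.
junction_points <- function(layout) {
  spec <- layout_spec(layout)
  R <- if (!is.null(spec)) spec$D_scaffold / 2 else
    max(sqrt(layout$x0^2 + layout$y0^2))
  layers <- sort(unique(layout$layer))
  out <- list()
  for (i in seq_along(layers)[-1]) {
    a <- layout[layout$layer == layers[i - 1L], ]
    b <- layout[layout$layer == layers[i], ]
    h0 <- if (a$orientation[1] == 0) a else if (b$orientation[1] == 0) b else NULL
    v0 <- if (a$orientation[1] == 90) a else if (b$orientation[1] == 90) b else NULL
    if (is.null(h0) || is.null(v0)) next  # parallel layers do not cross
    g <- expand.grid(y = h0$offset, x = v0$offset)
    g <- g[g$x^2 + g$y^2 < R^2, , drop = FALSE]
    if (nrow(g) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      x = g$x, y = g$y, z = (a$z[1] + b$z[1]) / 2)
  }
  if (length(out) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
  do.call(rbind, out)
}

#' Junction load index of a lattice design
#'
#' A dimensionless measure of how densely strand intersections load the
#' scaffold under compression: `n_junctions * D_strand^3 / V_envelope`.
#' Strand intersections concentrate compressive stress, and the volume of
#' material recruited at each intersection scales with the cube of the
#' strand diameter. The index drives the design-level amplitude of the
#' synthetic strain field (see [sample_strain_field()]).
#'
#' @param layout a [build_layout()] result (or a [scaffold_spec()], which is
#'   expanded first).
#' @return Numeric scalar.
#' @export
junction_load_index <- function(layout) {
  if (is_scaffold_spec(layout)) layout <- build_layout(layout)
  spec <- layout_spec(layout)
  if (is.null(spec))
    stop("layout carries no scaffold_spec attribute", call. = FALSE)
  nrow(junction_points(layout)) * spec$D_strand^3 / envelope_volume(spec)
}
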