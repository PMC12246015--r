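#' Sample a nodal surface mesh on the strand lattice
#'
#' Draws a quasi-uniform random sample of `n_nodes` points on the lateral
#' strand surfaces (strand picked with probability proportional to its
#' clipped lateral area, then uniform in axial position and circumferential
#' angle). Every node carries an equal area weight
#' `total lateral area / n_nodes`, so the weights sum to the strand surface
#' area exactly, and a junction proximity score
#' `exp(-dist_to_nearest_intersection / D_strand)` in \[0, 1\].
#'
#' The same node set is shared by the strain and the wall-shear-stress
#' fields produced from it (the conformal-interface contract).
#'
#' @param layout a [build_layout()] result (or a [scaffold_spec()]).
#' @param n_nodes number of surface nodes (>= 100).
#' @param seed RNG seed for the sampling.
#' @return A data frame of class `surface_mesh` with columns `id`, `x`,
#'   `y`, `z` (mm), `area` (mm^2) and `junction` (proximity score).
#'   Attributes: `spec`, `total_area`, `junctions` (crossing points) and
#'   `junction_load` (see [junction_load_index()]).
#' @export
surface_mesh <- function(layout, n_nodes = 5000, seed = 1L) {
  if (is_scaffold_spec(layout)) layout <- build_layout(layout)
  spec <- layout_spec(layout)
  if (is.null(spec))
    stop("layout carries no scaffold_spec attribute", call. = FALSE)
  if (n_nodes < 100)
    stop("resolution error: n_nodes must be >= 100", call. = FALSE)
  r <- spec$D_strand / 2
  lat_area <- pi * spec$D_strand * layout$chord
  total_area <- sum(lat_area)
  nodes <- with_seed(seed, {
    pick <- sample.int(nrow(layout), n_nodes, replace = TRUE,
                       prob = lat_area)
    ax <- stats::runif(n_nodes, -layout$chord[pick] / 2,
                       layout$chord[pick] / 2)
    th <- stats::runif(n_nodes, 0, 2 * pi)
    horiz <- layout$orientation[pick] == 0
    data.frame(
      id = seq_len(n_nodes),
      x = ifelse(horiz, ax, layout$offset[pick] + r * cos(th)),
      y = ifelse(horiz, layout$offset[pick] + r * cos(th), ax),
      z = layout$z[pick] + r * sin(th),
      area = total_area / n_nodes)
  })
  jp <- junction_points(layout)
  if (nrow(jp) > 0) {
    d2 <- rep(Inf, n_nodes)
    for (k in seq_len(nrow(jp)))
      d2 <- pmin(d2, (nodes$x - jp$x[k])^2 + (nodes$y - jp$y[k])^2 +
                   (nodes$z - jp$z[k])^2)
    nodes$junction <- exp(-sqrt(d2) / spec$D_strand)
  } else {
    nodes$junction <- 0
  }
  attr(nodes, "spec") <- spec
  attr(nodes, "total_area") <- total_area
  attr(nodes, "junctions") <- jp
  attr(nodes, "junction_load") <-
    nrow(jp) * spec$D_strand^3 / envelope_volume(spec)
  class(nodes) <- c("surface_mesh", "data.frame")
  nodes
}

#' @export
print.surface_mesh <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf(paste0("Surface mesh of '%s': %d nodes, %.0f mm^2 strand ",
                     "surface, %d strand junctions\n"),
              spec$name, nrow(x), attr(x, "total_area"),
              nrow(attr(x, "junctions"))))
  invisible(x)
}

mesh_spec <- function(mesh) attr(mesh, "spec")
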