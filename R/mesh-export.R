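#' Export a strand layout as a triangulated surface mesh
#'
#' Writes one closed tube (lateral surface plus two flat end caps) per
#' strand, triangulated with `n_segments` facets around the circumference.
#' Units are millimetres. Supported formats are ASCII STL and legacy VTK
#' polydata, both plain text and round-trip readable.
#'
#' @param layout a [build_layout()] result.
#' @param path output file path.
#' @param format `"stl"` or `"vtk"`.
#' @param n_segments circumferential facet count per tube (>= 3).
#' @return Invisibly, a list with `path`, `n_strands`, `n_triangles` and the
#'   total mesh `area` (mm^2).
#' @export
export_mesh <- function(layout, path, format = c("stl", "vtk"),
                        n_segments = 24) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unsupported format; supported formats: stl, vtk", call. = FALSE))
  if (!inherits(layout, "strand_layout") || nrow(layout) == 0)
    stop("empty or invalid layout: nothing to export", call. = FALSE)
  spec <- layout_spec(layout)
  r <- spec$D_strand / 2
  tri <- vector("list", nrow(layout))
  for (k in seq_len(nrow(layout))) {
    tri[[k]] <- strand_tube(layout[k, ], r, n_segments)
  }
  tri <- do.call(rbind, tri)       # n_tri x 9 matrix (v1 v2 v3 coords)
  area <- sum(triangle_areas(tri))
  if (format == "stl") write_stl(tri, path, name = spec$name)
  else write_vtk_poly(tri, path, name = spec$name)
  invisible(list(path = path, n_strands = nrow(layout),
                 n_triangles = nrow(tri), area = area))
}

# Triangulate one strand as a capped tube along its clipped chord.
strand_tube <- function(strand, r, nseg) {
  th <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  # local frame: axis u along the strand, (v, w) transverse
  if (strand$orientation == 0) {
    a0 <- c(strand$x0, strand$offset, strand$z)
    a1 <- c(strand$x1, strand$offset, strand$z)
    v <- c(0, 1, 0)
  } else {
    a0 <- c(strand$offset, strand$y0, strand$z)
    a1 <- c(strand$offset, strand$y1, strand$z)
    v <- c(1, 0, 0)
  }
  w <- c(0, 0, 1)
  ring <- function(cen) t(vapply(th, function(t)
    cen + r * cos(t) * v + r * sin(t) * w, numeric(3)))
  r0 <- ring(a0); r1 <- ring(a1)
  nxt <- c(seq_len(nseg)[-1], 1L)
  side1 <- cbind(r0, r1, r0[nxt, , drop = FALSE])
  side2 <- cbind(r1, r1[nxt, , drop = FALSE], r0[nxt, , drop = FALSE])
  cap0 <- cbind(matrix(a0, nseg, 3, byrow = TRUE), r0[nxt, , drop = FALSE], r0)
  cap1 <- cbind(matrix(a1, nseg, 3, byrow = TRUE), r1, r1[nxt, , drop = FALSE])
  rbind(side1, side2, cap0, cap1)
}

triangle_areas <- function(tri) {
  e1 <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
  e2 <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

write_stl <- function(tri, path, name = "scaffold") {
  e1 <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
  e2 <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), .Machine$double.eps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  block <- sprintf(
    paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
           "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
           "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
    nx / nn, ny / nn, nz / nn,
    tri[, 1], tri[, 2], tri[, 3], tri[, 4], tri[, 5], tri[, 6],
    tri[, 7], tri[, 8], tri[, 9])
  writeLines(block, con)
  writeLines(sprintf("endsolid %s", name), con)
}

write_vtk_poly <- function(tri, path, name = "scaffold") {
  n <- nrow(tri)
  pts <- matrix(t(tri), ncol = 3, byrow = TRUE)  # 3n x 3
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", 3 * n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", pts[, 1], pts[, 2], pts[, 3]), con)
  idx <- matrix(seq_len(3 * n) - 1L, ncol = 3, byrow = TRUE)
  writeLines(sprintf("POLYGONS %d %d", n, 4 * n), con)
  writeLines(sprintf("3 %d %d %d", idx[, 1], idx[, 2], idx[, 3]), con)
}
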