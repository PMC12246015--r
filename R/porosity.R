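#' Porosity and pore metrics of a strand layout
#'
#' Estimates the solid volume of the union of envelope-clipped strand
#' cylinders — material at interpenetrating layer junctions is counted once
#' — and reports the porosity
#' `1 - Volume_scaffold / Volume_total`, with
#' `Volume_total = pi * (D_scaffold/2)^2 * H_scaffold`.
#'
#' The default estimator discretises the envelope into z-slices of
#' thickness `resolution` (midpoint rule). Within each slice the strand
#' cylinders reduce to axis-aligned bands across the envelope circle, whose
#' union area is evaluated in closed form (chord integrals plus exact
#' rectangle-in-disc crossing areas), so the only discretisation error is
#' across z and a 25 um resolution runs in well under a second per design.
#' The reported standard error is the refinement estimate
#' `|p(res) - p(2 res)|`. The alternative Monte-Carlo estimator samples
#' `n_samples` points uniformly in the envelope under `seed` and reports
#' the binomial standard error.
#'
#' @param layout a [build_layout()] result (or a [scaffold_spec()]).
#' @param resolution voxel edge length, mm; must not exceed `D_strand / 10`.
#' @param method `"voxel"` (deterministic, default) or `"montecarlo"`.
#' @param n_samples Monte-Carlo sample count.
#' @param seed RNG seed for the Monte-Carlo estimator.
#' @return An object of class `pore_metrics`: list with `porosity`,
#'   `solid_volume`, `total_volume` (mm^3), `pore_window_area` (mm^2),
#'   `D_pore` (um), `se`, `method`, `resolution`.
#' @examples
#' m <- pore_metrics(build_layout(scaffold_spec(N_H = 7, N_V = 9)),
#'                   resolution = 0.05)
#' m$porosity
#' @export
pore_metrics <- function(layout, resolution = 0.025,
                         method = c("voxel", "montecarlo"),
                         n_samples = 2e5, seed = NULL) {
  method <- match.arg(method)
  if (is_scaffold_spec(layout)) layout <- build_layout(layout)
  spec <- layout_spec(layout)
  if (is.null(spec))
    stop("layout carries no scaffold_spec attribute", call. = FALSE)
  total <- envelope_volume(spec)
  if (nrow(layout) == 0) {
    warning("empty layout: porosity is 1")
    solid <- 0; se <- 0
  } else if (method == "voxel") {
    if (resolution > spec$D_strand / 10 + 1e-12)
      stop(sprintf(paste0("resolution %.3g mm too coarse for D_strand = ",
                          "%.3g mm (must be <= D_strand/10)"),
                   resolution, spec$D_strand), call. = FALSE)
    solid <- voxel_solid_volume(layout, spec, resolution)
    coarse <- voxel_solid_volume(layout, spec, 2 * resolution)
    se <- abs(solid - coarse) / total
  } else {
    est <- mc_solid_volume(layout, spec, n_samples, seed)
    solid <- est[["volume"]]
    se <- est[["se"]] / total
  }
  window <- tryCatch((spec$Y - spec$D_strand)^2, error = function(e) NA_real_)
  dpore <- tryCatch(pore_equivalent_diameter(spec), error = function(e) NA_real_)
  structure(
    list(porosity = 1 - solid / total, solid_volume = solid,
         total_volume = total, pore_window_area = window, D_pore = dpore,
         se = se, method = method,
         resolution = if (method == "voxel") resolution else n_samples,
         design = spec$name),
    class = "pore_metrics")
}

#' @export
print.pore_metrics <- function(x, ...) {
  cat(sprintf("Pore metrics of '%s' (%s)\n", x$design, x$method))
  cat(sprintf("  porosity: %.1f%% (se %.2g)\n", 100 * x$porosity, 100 * x$se))
  cat(sprintf("  solid / total volume: %.1f / %.1f mm^3\n",
              x$solid_volume, x$total_volume))
  if (is.finite(x$D_pore))
    cat(sprintf("  pore window %.3f mm^2, D_pore %.0f um\n",
                x$pore_window_area, x$D_pore))
  invisible(x)
}

# Slice integrator for the union of strand cylinders inside the envelope.
# At a slice height z every active strand occupies the band
# |coord - offset| <= w(z) = sqrt(r^2 - (z - z_layer)^2) transverse to its
# axis: 0-degree strands band the y axis, 90-degree strands the x axis.
# The in-plane area of (Y-bands union X-bands) inside the envelope circle
# is evaluated in closed form (chord integrals for the bands, exact
# rectangle-in-disc areas for the band crossings, which also removes the
# double count at interpenetrating junctions); only the z direction is
# discretised, with `res` as the slice thickness (midpoint rule).
voxel_solid_volume <- function(layout, spec, res) {
  R <- spec$D_scaffold / 2
  r <- spec$D_strand / 2
  zs <- seq(res / 2, spec$H_scaffold - res / 2, by = res)
  solid <- 0
  for (z in zs) {
    act <- abs(z - layout$z) < r
    if (!any(act)) next
    w <- sqrt(r^2 - (z - layout$z[act])^2)
    offs <- layout$offset[act]
    oris <- layout$orientation[act]
    ybands <- merge_intervals(offs[oris == 0] - w[oris == 0],
                              offs[oris == 0] + w[oris == 0], R)
    xbands <- merge_intervals(offs[oris != 0] - w[oris != 0],
                              offs[oris != 0] + w[oris != 0], R)
    area <- sum(chord_integral(R, ybands$a, ybands$b)) +
      sum(chord_integral(R, xbands$a, xbands$b))
    if (nrow(ybands) && nrow(xbands)) {
      for (i in seq_len(nrow(ybands)))
        area <- area - sum(vapply(seq_len(nrow(xbands)), function(j)
          circle_rect_area(R, xbands$a[j], xbands$b[j],
                           ybands$a[i], ybands$b[i]), numeric(1)))
    }
    solid <- solid + area
  }
  solid * res
}

# union of [a_i, b_i] clipped to [-R, R], returned as disjoint intervals
merge_intervals <- function(a, b, R) {
  a <- pmax(a, -R); b <- pmin(b, R)
  keep <- b > a
  a <- a[keep]; b <- b[keep]
  if (length(a) == 0) return(data.frame(a = numeric(0), b = numeric(0)))
  o <- order(a)
  a <- a[o]; b <- b[o]
  ma <- a[1]; mb <- b[1]; outa <- c(); outb <- c()
  for (k in seq_along(a)[-1]) {
    if (a[k] <= mb) mb <- max(mb, b[k])
    else { outa <- c(outa, ma); outb <- c(outb, mb); ma <- a[k]; mb <- b[k] }
  }
  data.frame(a = c(outa, ma), b = c(outb, mb))
}

# int_a^b 2*sqrt(R^2 - t^2) dt  (area of the full-width band inside the disc)
chord_integral <- function(R, a, b) {
  F <- function(t) t * sqrt(pmax(0, R^2 - t^2)) + R^2 * asin(pmin(1, pmax(-1, t / R)))
  F(b) - F(a)
}

# exact area of the axis-aligned rectangle [x1,x2] x [y1,y2] inside the
# disc of radius R centred at the origin
circle_rect_area <- function(R, x1, x2, y1, y2) {
  x1 <- max(x1, -R); x2 <- min(x2, R)
  if (x2 <= x1 || y1 >= R || y2 <= -R) return(0)
  # split where the circle crosses the horizontal edges
  cuts <- c(x1, x2)
  for (yy in c(y1, y2)) {
    if (abs(yy) < R) {
      xc <- sqrt(R^2 - yy^2)
      cuts <- c(cuts, -xc, xc)
    }
  }
  cuts <- sort(unique(pmin(pmax(cuts, x1), x2)))
  # antiderivative of sqrt(R^2 - x^2)
  G <- function(t) 0.5 * (t * sqrt(pmax(0, R^2 - t^2)) +
                            R^2 * asin(pmin(1, pmax(-1, t / R))))
  total <- 0
  for (k in seq_len(length(cuts) - 1)) {
    lo <- cuts[k]; hi <- cuts[k + 1]
    if (hi - lo < 1e-15) next
    xm <- (lo + hi) / 2
    ym <- sqrt(max(0, R^2 - xm^2))
    top <- min(y2, ym); bot <- max(y1, -ym)
    if (top <= bot) next
    # on this piece each edge is either the straight rectangle edge or the arc
    ttop <- if (y2 <= ym) y2 * (hi - lo) else G(hi) - G(lo)
    tbot <- if (y1 >= -ym) y1 * (hi - lo) else -(G(hi) - G(lo))
    total <- total + (ttop - tbot)
  }
  total
}

mc_solid_volume <- function(layout, spec, n_samples, seed) {
  R <- spec$D_scaffold / 2
  r <- spec$D_strand / 2
  with_seed(seed, {
    rad <- R * sqrt(stats::runif(n_samples))
    th <- stats::runif(n_samples, 0, 2 * pi)
    x <- rad * cos(th); y <- rad * sin(th)
    z <- stats::runif(n_samples, 0, spec$H_scaffold)
    inside <- rep(FALSE, n_samples)
    for (k in seq_len(nrow(layout))) {
      lat <- if (layout$orientation[k] == 0) y else x
      inside <- inside |
        ((lat - layout$offset[k])^2 + (z - layout$z[k])^2 <= r^2)
    }
    p <- mean(inside)
    vol <- envelope_volume(spec)
    c(volume = p * vol, se = sqrt(p * (1 - p) / n_samples) * vol)
  })
}

#' Minimal equivalent pore diameter
#'
#' Diameter of the imaginary circle whose area equals the minimum pore
#' window bounded by four strands: two parallel strands of one layer (gap
#' `Y - D_strand`) and the two orthogonal strands of the adjacent layers
#' bounding the same window, giving a projected open area of
#' `(Y - D_strand)^2`. Hence `D_pore = 2 (Y - D_strand) / sqrt(pi)`,
#' reported in micrometres.
#'
#' @param spec a [scaffold_spec()].
#' @return `D_pore` in um.
#' @examples
#' pore_equivalent_diameter(scaffold_spec(N_H = 9, N_V = 9))  # ~464 um
#' @export
pore_equivalent_diameter <- function(spec) {
  stopifnot(is_scaffold_spec(spec))
  gap <- spec$Y - spec$D_strand
  if (gap < 0)
    stop("zero pore window: Y < D_strand", call. = FALSE)
  1000 * 2 * gap / sqrt(pi)
}
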