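#' Calibrate the surrogate against reference peak averages
#'
#' Solves the surrogate's four free coefficients from the peak
#' surface-averaged OSS and WSS of two reference designs (by default the
#' most- and least-porous step-1 lattices):
#'
#' * strain channel: the expected peak node mean is
#'   `A * T * (1 + a * chi_d)` with `A` the peak compression fraction and
#'   `chi_d` the design's junction load index, so the two OSS anchors give
#'   `(T, a)` in closed form;
#' * WSS channel: the expected peak area-weighted mean is
#'   `g * tau0_d^p` with `tau0_d = 8 mu u_d / D_pore_d` the peak Poiseuille
#'   channel stress, so the two WSS anchors give `(g, p)` in closed form.
#'
#' The solved parameters are design-independent and are frozen once into
#' the package defaults (`inst/extdata/surrogate-defaults.yaml`); they are
#' configuration, not code constants.
#'
#' @param low,high the two anchor designs ([scaffold_spec()] objects),
#'   ordered as the anchor values are.
#' @param anchors list with numeric `oss` (peak OSS_avg, dimensionless) and
#'   `wss` (peak WSS_avg, mPa), each of length 2 in `(low, high)` order.
#' @param protocol a [loading_protocol()].
#' @param fluid a [fluid_properties()].
#' @param sigma,depth_attenuation,seed passed through to the result.
#' @return A [surrogate_params()] object with a `calibration` attribute
#'   recording the anchor quantities.
#' @export
calibrate_surrogate <- function(low = scaffold_spec(6, 9, step = 1),
                                high = scaffold_spec(10, 9, step = 1),
                                anchors = list(oss = c(0.030, 0.046),
                                               wss = c(7.09, 18.74)),
                                protocol = loading_protocol(),
                                fluid = fluid_properties(),
                                sigma = 0.2, depth_attenuation = 0.5,
                                seed = 1L) {
  stopifnot(length(anchors$oss) == 2, length(anchors$wss) == 2)
  geom <- function(spec) {
    layout <- build_layout(spec)
    list(chi = junction_load_index(layout),
         porosity = pore_metrics(layout)$porosity,
         dpore_mm = pore_equivalent_diameter(spec) / 1000)
  }
  gl <- geom(low); gh <- geom(high)
  A <- protocol$amplitude_fraction
  ratio <- anchors$oss[2] / anchors$oss[1]
  a <- (ratio - 1) / (gh$chi - ratio * gl$chi)
  if (!is.finite(a) || a < 0)
    stop("OSS anchors are not reachable: junction load indices too close",
         call. = FALSE)
  transfer <- anchors$oss[1] / (A * (1 + a * gl$chi))
  vmax <- protocol$amplitude * pi * protocol$frequency   # mm/s
  tau0 <- function(g) 8000 * fluid$viscosity * (vmax / g$porosity) / g$dpore_mm
  t_l <- tau0(gl); t_h <- tau0(gh)
  p <- log(anchors$wss[2] / anchors$wss[1]) / log(t_h / t_l)
  g <- anchors$wss[1] / t_l^p
  out <- surrogate_params(strain_transfer = transfer,
                          junction_amplification = a,
                          wss_gain = g, wss_exponent = p,
                          depth_attenuation = depth_attenuation,
                          sigma = sigma, seed = seed)
  attr(out, "calibration") <- list(
    low = low$name, high = high$name, anchors = anchors,
    chi = c(gl$chi, gh$chi), porosity = c(gl$porosity, gh$porosity),
    tau0_mpa = c(t_l, t_h))
  out
}
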