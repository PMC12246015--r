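#' Culture-medium fluid properties
#'
#' @param density kg/m^3.
#' @param viscosity dynamic viscosity, Pa s.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1000, viscosity = 1.45e-3) {
  stopifnot_scalar(density, "density", positive = TRUE)
  stopifnot_scalar(viscosity, "viscosity", positive = TRUE)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Reduced-order surrogate parameters
#'
#' Parameters of the synthetic-field generator that stands in for the
#' coupled FE/CFD solver. The strain channel has a baseline transfer factor
#' and a junction amplification acting on the dimensionless junction load
#' index of the design; the wall-shear-stress channel has a gain and an
#' exponent acting on the Poiseuille channel stress `8 mu u / D_pore`.
#' Per-node heterogeneity is multiplicative mean-one lognormal with spread
#' `sigma`, and wall shear stress is attenuated towards the scaffold core
#' by `depth_attenuation`.
#'
#' The default values shipped with the package were produced once by
#' [calibrate_surrogate()] against the step-1 reference peaks and then
#' frozen; see `default_surrogate_params()`.
#'
#' @param strain_transfer baseline compression-to-OSS transfer factor
#'   (dimensionless).
#' @param junction_amplification gain on the junction load index (>= 1).
#' @param wss_gain WSS channel gain (mPa^(1 - wss_exponent)).
#' @param wss_exponent exponent on the channel stress (0 < p <= 1).
#' @param depth_attenuation fractional WSS reduction at the scaffold axis
#'   (0 = none, towards 1 = fully shielded core).
#' @param sigma lognormal heterogeneity spread (>= 0).
#' @param seed RNG seed recorded with generated fields.
#' @return An object of class `surrogate_params`.
#' @export
surrogate_params <- function(strain_transfer = 0.387,
                             junction_amplification = 2.37,
                             wss_gain = 1.65, wss_exponent = 0.556,
                             depth_attenuation = 0.5, sigma = 0.2,
                             seed = 1L) {
  stopifnot_scalar(strain_transfer, "strain_transfer", positive = TRUE)
  stopifnot_scalar(junction_amplification, "junction_amplification")
  if (junction_amplification < 1)
    stop("'junction_amplification' must be >= 1", call. = FALSE)
  stopifnot_scalar(wss_gain, "wss_gain", positive = TRUE)
  stopifnot_scalar(wss_exponent, "wss_exponent", positive = TRUE)
  stopifnot_scalar(depth_attenuation, "depth_attenuation")
  if (depth_attenuation < 0 || depth_attenuation >= 1)
    stop("'depth_attenuation' must be in [0, 1)", call. = FALSE)
  stopifnot_scalar(sigma, "sigma")
  if (sigma < 0) stop("'sigma' must be >= 0", call. = FALSE)
  structure(
    list(strain_transfer = strain_transfer,
         junction_amplification = junction_amplification,
         wss_gain = wss_gain, wss_exponent = wss_exponent,
         depth_attenuation = depth_attenuation, sigma = sigma,
         seed = as.integer(seed)),
    class = "surrogate_params")
}

#' @rdname surrogate_params
#' @export
default_surrogate_params <- function() {
  path <- system.file("extdata", "surrogate-defaults.yaml",
                      package = "scaffoldmech")
  vals <- yaml::read_yaml(path)
  do.call(surrogate_params, vals[setdiff(names(vals), "calibration")])
}

#' Synthetic nodal octahedral-shear-strain field
#'
#' One sample of the surrogate strain field at a given compression level:
#' `OSS_node = compression * transfer * (1 + a * chi * g_node) * noise`,
#' where `chi` is the design's junction load index, `g_node` the mean-one
#' junction-proximity modulation (strain concentrates at strand
#' intersections) and `noise` mean-one lognormal heterogeneity. The
#' arithmetic node mean is therefore `compression * transfer *
#' (1 + a * chi)` in expectation and scales exactly linearly with
#' compression; zero compression gives an all-zero field.
#'
#' @param mesh a [surface_mesh()].
#' @param compression current compression fraction (piston displacement /
#'   scaffold height), >= 0.
#' @param params a [surrogate_params()].
#' @param node_noise optional pre-drawn per-node multipliers (used by
#'   [generate_cycle()] to keep heterogeneity frozen over the cycle);
#'   drawn from `params$seed` when `NULL`.
#' @return Numeric vector of nodal OSS values (dimensionless).
#' @export
sample_strain_field <- function(mesh, compression, params = default_surrogate_params(),
                                node_noise = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!is.finite(compression) || compression < 0)
    stop("'compression' must be >= 0", call. = FALSE)
  if (is.null(node_noise))
    node_noise <- with_seed(params$seed, lognormal_noise(nrow(mesh), params$sigma))
  compression * params$strain_transfer *
    (1 + params$junction_amplification * attr(mesh, "junction_load") *
       junction_modulation(mesh)) * node_noise
}

# mean-one spatial modulation from the junction proximity score
junction_modulation <- function(mesh) {
  s <- mesh$junction
  m <- mean(s)
  if (m < 1e-12) return(rep(0, length(s)))   # no intersections
  s / m
}

#' Synthetic nodal wall-shear-stress field
#'
#' Reduced-order squeeze-flow model of the compression-induced wall shear
#' stress on the strand surfaces. The piston displaces fluid through the
#' open pore fraction, giving a superficial pore speed
#' `u = |piston speed| / porosity`; the corresponding Poiseuille channel
#' stress through the minimal pore window is `tau0 = 8 mu u / D_pore`. The
#' nodal field is `gain * tau0^p`, attenuated towards the scaffold core
#' (interior regions see less flow) and modulated by mean-one lognormal
#' heterogeneity; the attenuation profile is normalised to area-weighted
#' mean one so the surface average equals `gain * tau0^p` in expectation,
#' linear in piston speed for `p = 1` and monotone in it always. Zero
#' piston speed gives an all-zero field.
#'
#' @param mesh a [surface_mesh()].
#' @param piston_speed absolute piston speed, mm/s.
#' @param fluid a [fluid_properties()].
#' @param params a [surrogate_params()].
#' @param porosity open pore fraction of the design; computed by
#'   [pore_metrics()] when `NULL`.
#' @param node_noise optional pre-drawn per-node multipliers (see
#'   [sample_strain_field()]).
#' @return Numeric vector of nodal WSS values, mPa.
#' @export
sample_wss_field <- function(mesh, piston_speed, fluid = fluid_properties(),
                             params = default_surrogate_params(),
                             porosity = NULL, node_noise = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  spec <- mesh_spec(mesh)
  dpore_mm <- pore_equivalent_diameter(spec) / 1000
  if (dpore_mm <= 0)
    stop("geometry error: D_pore is zero", call. = FALSE)
  if (is.null(porosity))
    porosity <- pore_metrics(build_layout(spec))$porosity
  if (is.null(node_noise))
    node_noise <- with_seed(params$seed + 1L,
                            lognormal_noise(nrow(mesh), params$sigma))
  u <- abs(piston_speed) / porosity                  # mm/s
  tau0 <- 8000 * fluid$viscosity * u / dpore_mm      # mPa
  params$wss_gain * tau0^params$wss_exponent *
    depth_profile(mesh, params$depth_attenuation) * node_noise
}

# radial attenuation, area-weight-normalised to mean one
depth_profile <- function(mesh, k) {
  if (k <= 0) return(rep(1, nrow(mesh)))
  spec <- mesh_spec(mesh)
  rho <- sqrt(mesh$x^2 + mesh$y^2) / (spec$D_scaffold / 2)
  raw <- 1 - k * (1 - pmin(rho, 1))
  raw / stats::weighted.mean(raw, mesh$area)
}

#' Reynolds number based on the strand diameter
#'
#' `Re = rho * u * D_strand / mu` with `u` in m/s.
#'
#' @param u flow speed, m/s (>= 0).
#' @param spec a [scaffold_spec()] (provides `D_strand`).
#' @param fluid a [fluid_properties()].
#' @return Dimensionless Reynolds number; vectorised over `u`.
#' @export
reynolds_number <- function(u, spec, fluid = fluid_properties()) {
  if (any(u < 0)) stop("'u' must be >= 0", call. = FALSE)
  stopifnot(is_scaffold_spec(spec))
  fluid$density * u * (spec$D_strand / 1000) / fluid$viscosity
}
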