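#' Read, validate and write run configurations
#'
#' The YAML run configuration collects every tunable of the pipeline.
#' Recognised top-level blocks (all optional; missing values take the
#' defaults shown by `default_config()`):
#'
#' * `design` — a single design block or list of blocks with keys `name`,
#'   `D_scaffold_mm`, `H_scaffold_mm`, `D_strand_um`, `N_H`, `N_V` and
#'   optional explicit spans `Y_mm`, `h_mm`;
#' * `material` — `mu_kpa`, `alpha`, `d` (Ogden terms);
#' * `protocol` — `frequency_hz`, `amplitude_fraction`, `timestep_s`;
#' * `fluid` — `density_kg_m3`, `viscosity_pa_s`;
#' * `stimulus` — `a`, `b_mpa`;
#' * `surrogate` — the [surrogate_params()] fields;
#' * `sweep` — `NH_range`, `NV_set`, `reference`, `criterion`,
#'   `stop_threshold_pct`, `d_strand_bounds_um`, `n_nodes`;
#' * `seed`, `output_dir`.
#'
#' Unknown keys are rejected by name. Units in files are mm, s and mPa
#' except where a key name says otherwise (`D_strand_um`,
#' `viscosity_pa_s`).
#'
#' @param path YAML file path.
#' @return `read_config()` returns a validated `run_config` list with all
#'   defaults filled in; `write_config()` writes one back and returns the
#'   path invisibly; `default_config()` returns the defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' @rdname read_config
#' @export
default_config <- function() {
  sp <- default_surrogate_params()
  structure(list(
    design = NULL,
    material = list(mu_kpa = -5.8, alpha = -1.3, d = 0),
    protocol = list(frequency_hz = 1, amplitude_fraction = 0.05,
                    timestep_s = 0.01),
    fluid = list(density_kg_m3 = 1000, viscosity_pa_s = 1.45e-3),
    stimulus = list(a = 0.0375, b_mpa = 10),
    surrogate = list(strain_transfer = sp$strain_transfer,
                     junction_amplification = sp$junction_amplification,
                     wss_gain = sp$wss_gain, wss_exponent = sp$wss_exponent,
                     depth_attenuation = sp$depth_attenuation,
                     sigma = sp$sigma, seed = sp$seed),
    sweep = list(NH_range = c(6L, 10L), NV_set = c(8L, 10L, 11L),
                 reference = NULL, criterion = "cartilage",
                 stop_threshold_pct = 1,
                 d_strand_bounds_um = c(500, 800), n_nodes = 5000L),
    seed = 1L,
    output_dir = "."), class = "run_config")
}

DESIGN_KEYS <- c("name", "D_scaffold_mm", "H_scaffold_mm", "D_strand_um",
                 "N_H", "N_V", "Y_mm", "h_mm")

validate_config <- function(raw) {
  cfg <- default_config()
  known <- names(cfg)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (block in setdiff(intersect(names(raw), known),
                        c("design", "seed", "output_dir"))) {
    bad <- setdiff(names(raw[[block]]), names(cfg[[block]]))
    if (length(bad))
      stop(sprintf("unknown config key(s) in '%s': %s", block,
                   paste(bad, collapse = ", ")), call. = FALSE)
    cfg[[block]][names(raw[[block]])] <- raw[[block]]
  }
  if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
  if (!is.null(raw$output_dir)) cfg$output_dir <- raw$output_dir
  if (!is.null(raw$design)) {
    blocks <- if (!is.null(names(raw$design))) list(raw$design)
    else raw$design
    for (b in blocks) {
      bad <- setdiff(names(b), DESIGN_KEYS)
      if (length(bad))
        stop(sprintf("unknown config key(s) in 'design': %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
    }
    cfg$design <- blocks
  }
  cfg
}

#' @rdname read_config
#' @param config a `run_config` list.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Convert a config design block to a scaffold_spec
#'
#' @param block named list with the `design` keys of [read_config()].
#' @return A [scaffold_spec()].
#' @export
design_from_config <- function(block) {
  scaffold_spec(
    N_H = block$N_H, N_V = block$N_V,
    D_scaffold = block$D_scaffold_mm %||% 10,
    H_scaffold = block$H_scaffold_mm %||% 4.8,
    D_strand = (block$D_strand_um %||% 700) / 1000,
    Y = block$Y_mm, h = block$h_mm, name = block$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_protocol <- function(cfg, scaffold_height = 4.8) {
  loading_protocol(frequency = cfg$protocol$frequency_hz,
                   amplitude_fraction = cfg$protocol$amplitude_fraction,
                   scaffold_height = scaffold_height,
                   timestep = cfg$protocol$timestep_s)
}

config_fluid <- function(cfg) {
  fluid_properties(density = cfg$fluid$density_kg_m3,
                   viscosity = cfg$fluid$viscosity_pa_s)
}

config_surrogate <- function(cfg) do.call(surrogate_params, cfg$surrogate)

config_consts <- function(cfg) {
  stimulus_constants(a = cfg$stimulus$a, b = cfg$stimulus$b_mpa)
}

#' Stable hash of a run configuration
#'
#' MD5 of the canonical YAML serialisation; embedded in output files for
#' provenance.
#'
#' @param config a `run_config` list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
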