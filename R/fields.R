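#' Time series of a nodal surface field
#'
#' Container for one conformal nodal field (OSS or WSS) sampled over a
#' loading cycle: a nodes-by-times value matrix plus the shared node table.
#'
#' @param values numeric matrix, nodes x times.
#' @param times time stamps, s.
#' @param mesh the [surface_mesh()] the values live on.
#' @param field `"oss"` or `"wss"`.
#' @param seed RNG seed recorded with the series.
#' @return An object of class `field_series`.
#' @export
field_series <- function(values, times, mesh, field = c("oss", "wss"),
                         seed = NA_integer_) {
  field <- match.arg(field)
  stopifnot(inherits(mesh, "surface_mesh"))
  values <- as.matrix(values)
  if (nrow(values) != nrow(mesh) || ncol(values) != length(times))
    stop("'values' must be nodes x times", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop(sprintf("%s values must be finite and >= 0", toupper(field)),
         call. = FALSE)
  structure(
    list(values = values, times = times, mesh = mesh, field = field,
         design = mesh_spec(mesh)$name, seed = seed),
    class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("%s field series of '%s': %d nodes x %d times (t in [%g, %g] s)\n",
              toupper(x$field), x$design, nrow(x$values), length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Generate conformal strain and wall-shear-stress fields over one cycle
#'
#' Runs the reduced-order surrogate over a full loading cycle: at each
#' time-step the compression fraction drives [sample_strain_field()] and
#' the piston speed drives [sample_wss_field()], both on the same shared
#' node set (the conformal-interface contract). Per-node heterogeneity is
#' drawn once per field and frozen over the cycle, so the whole result is
#' reproducible bit-for-bit under a fixed seed.
#'
#' @param spec a [scaffold_spec()].
#' @param protocol a [loading_protocol()]; its `scaffold_height` must match
#'   the design.
#' @param fluid a [fluid_properties()].
#' @param params a [surrogate_params()].
#' @param n_nodes surface node count.
#' @param seed RNG seed; defaults to `params$seed`.
#' @param mesh optional pre-built [surface_mesh()] (skips sampling).
#' @param porosity optional pre-computed porosity (skips voxelisation).
#' @return A list of class `cycle_fields` with elements `strain` and `wss`
#'   ([field_series()] objects), `mesh`, `times`, `porosity` and `seed`.
#' @examples
#' \donttest{
#' cyc <- generate_cycle(scaffold_spec(N_H = 7, N_V = 9, step = 0),
#'                       n_nodes = 500, seed = 1)
#' }
#' @export
generate_cycle <- function(spec, protocol = NULL, fluid = fluid_properties(),
                           params = default_surrogate_params(),
                           n_nodes = 5000, seed = params$seed, mesh = NULL,
                           porosity = NULL) {
  stopifnot(is_scaffold_spec(spec))
  if (is.null(protocol))
    protocol <- loading_protocol(scaffold_height = spec$H_scaffold)
  if (abs(protocol$scaffold_height - spec$H_scaffold) > 1e-9)
    stop("protocol scaffold_height does not match the design", call. = FALSE)
  layout <- build_layout(spec)
  if (is.null(mesh)) mesh <- surface_mesh(layout, n_nodes, seed = seed)
  else if (!identical(mesh_spec(mesh)$name, spec$name))
    stop("conformality error: mesh was built for a different design",
         call. = FALSE)
  if (is.null(porosity)) porosity <- pore_metrics(layout)$porosity
  noise <- with_seed(seed, list(
    strain = lognormal_noise(nrow(mesh), params$sigma),
    wss = lognormal_noise(nrow(mesh), params$sigma)))
  times <- protocol_times(protocol)
  comp <- piston_displacement(protocol, times) / protocol$scaffold_height
  speed <- abs(piston_velocity(protocol, times))
  oss <- vapply(comp, function(cc)
    sample_strain_field(mesh, cc, params, node_noise = noise$strain),
    numeric(nrow(mesh)))
  wss <- vapply(speed, function(v)
    sample_wss_field(mesh, v, fluid, params, porosity = porosity,
                     node_noise = noise$wss),
    numeric(nrow(mesh)))
  structure(
    list(strain = field_series(oss, times, mesh, "oss", seed),
         wss = field_series(wss, times, mesh, "wss", seed),
         mesh = mesh, times = times, porosity = porosity, seed = seed,
         design = spec$name),
    class = "cycle_fields")
}

#' @export
print.cycle_fields <- function(x, ...) {
  cat(sprintf(paste0("Synthetic FSI cycle for '%s': %d nodes x %d times, ",
                     "porosity %.1f%%, seed %d\n"),
              x$design, nrow(x$mesh), length(x$times), 100 * x$porosity,
              x$seed))
  invisible(x)
}

FIELD_SCHEMA <- "1.0"

#' Read and write nodal field CSV files
#'
#' Long-format plain-text exchange schema for conformal nodal fields:
#' columns `node_id, x_mm, y_mm, z_mm, area_mm2, t_s, oss, wss_mpa`,
#' preceded by `#`-comment header lines carrying the schema version, design
#' name, seed and configuration hash. Any solver export matching this
#' schema can be fed to the mechanoregulation stage. Readers reject files
#' whose schema major version differs.
#'
#' @param cycle a [generate_cycle()] result.
#' @param path file path.
#' @param config_hash optional provenance hash stored in the header.
#' @param overwrite overwrite an existing file?
#' @return `write_field_csv()` returns the path invisibly;
#'   `read_field_csv()` returns a list with `strain` and `wss`
#'   [field_series()] objects and the header metadata.
#' @export
write_field_csv <- function(cycle, path, config_hash = NA_character_,
                            overwrite = FALSE) {
  stopifnot(inherits(cycle, "cycle_fields"))
  if (file.exists(path) && !overwrite)
    stop(sprintf("'%s' exists; set overwrite = TRUE to replace it", path),
         call. = FALSE)
  mesh <- cycle$mesh
  nt <- length(cycle$times)
  long <- data.frame(
    node_id = rep(mesh$id, nt),
    x_mm = rep(mesh$x, nt), y_mm = rep(mesh$y, nt), z_mm = rep(mesh$z, nt),
    area_mm2 = rep(mesh$area, nt),
    t_s = rep(cycle$times, each = nrow(mesh)),
    oss = as.vector(cycle$strain$values),
    wss_mpa = as.vector(cycle$wss$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# scaffoldmech nodal field schema %s", FIELD_SCHEMA),
    sprintf("# design: %s", cycle$design),
    sprintf("# seed: %d", cycle$seed),
    sprintf("# units: mm, s, mPa, dimensionless strain"),
    sprintf("# config_hash: %s", config_hash)), con)
  utils::write.table(long, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  head <- readLines(path, n = 10)
  head <- head[startsWith(head, "#")]
  ver <- sub(".*schema ", "", head[grepl("schema", head)][1])
  if (is.na(ver) || strsplit(ver, ".", fixed = TRUE)[[1]][1] !=
      strsplit(FIELD_SCHEMA, ".", fixed = TRUE)[[1]][1])
    stop(sprintf("unsupported field schema version '%s'", ver), call. = FALSE)
  meta <- function(key) {
    ln <- head[grepl(paste0("# ", key, ":"), head, fixed = TRUE)]
    if (length(ln) == 0) NA_character_ else sub(paste0("# ", key, ": "), "", ln[1])
  }
  long <- utils::read.csv(path, comment.char = "#")
  times <- sort(unique(long$t_s))
  first <- long[long$t_s == times[1], ]
  ord <- order(first$node_id)
  nodes <- data.frame(id = first$node_id[ord], x = first$x_mm[ord],
                      y = first$y_mm[ord], z = first$z_mm[ord],
                      area = first$area_mm2[ord])
  nodes$junction <- NA_real_
  attr(nodes, "spec") <- scaffold_spec(N_H = 2, N_V = 1,
                                       name = meta("design"))
  attr(nodes, "total_area") <- sum(nodes$area)
  attr(nodes, "junctions") <- data.frame(x = numeric(0), y = numeric(0),
                                         z = numeric(0))
  attr(nodes, "junction_load") <- NA_real_
  class(nodes) <- c("surface_mesh", "data.frame")
  shape <- function(col) {
    m <- matrix(NA_real_, nrow(nodes), length(times))
    for (j in seq_along(times)) {
      blk <- long[long$t_s == times[j], ]
      m[, j] <- blk[[col]][order(blk$node_id)]
    }
    m
  }
  seed <- suppressWarnings(as.integer(meta("seed")))
  list(strain = field_series(shape("oss"), times, nodes, "oss", seed),
       wss = field_series(shape("wss_mpa"), times, nodes, "wss", seed),
       design = meta("design"), seed = seed,
       config_hash = meta("config_hash"))
}
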