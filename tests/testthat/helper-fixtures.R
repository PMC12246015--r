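# shared fixtures: all built in code, no files

# hand-built layout with arbitrary strand placement (bypasses the lattice
# span conventions; used for analytic oracles)
manual_layout <- function(spec, offset, z, orientation) {
  R <- spec$D_scaffold / 2
  half <- sqrt(pmax(0, R^2 - offset^2))
  df <- data.frame(
    layer = seq_along(offset), orientation = orientation, offset = offset,
    z = z, chord = 2 * half,
    x0 = ifelse(orientation == 0, -half, offset),
    y0 = ifelse(orientation == 0, offset, -half),
    x1 = ifelse(orientation == 0, half, offset),
    y1 = ifelse(orientation == 0, offset, half))
  attr(df, "spec") <- spec
  class(df) <- c("strand_layout", "data.frame")
  df
}

empty_layout <- function(spec = original_scaffold()) {
  manual_layout(spec, numeric(0), numeric(0), numeric(0))
}

# one diametral 1 mm strand in a 10 x 10 envelope; clipped volume has the
# closed-form oracle integral 2*sqrt(R^2-y^2) * 2*sqrt(r^2-y^2) over |y|<r
single_strand_fixture <- function() {
  spec <- scaffold_spec(N_H = 2, N_V = 1, D_scaffold = 10, H_scaffold = 10,
                        D_strand = 1, Y = 5, h = 10, name = "single-strand")
  list(spec = spec, layout = manual_layout(spec, 0, 5, 0))
}

quick_cycle <- function(nh = 7, nv = 9, n_nodes = 800, seed = 11,
                        timestep = 0.02, step = 0, params = NULL) {
  spec <- scaffold_spec(nh, nv, step = step)
  if (is.null(params)) params <- default_surrogate_params()
  generate_cycle(spec,
                 loading_protocol(scaffold_height = spec$H_scaffold,
                                  timestep = timestep),
                 n_nodes = n_nodes, seed = seed, params = params)
}

# minimal synthetic sweep_report for selection-rule tests
fake_report <- function(cartilage, N_V = seq_along(cartilage)) {
  nms <- sprintf("D%d", seq_along(cartilage))
  summaries <- lapply(seq_along(cartilage), function(i) {
    pct <- c(very_low = 0, bone = 100 - cartilage[i],
             cartilage = cartilage[i], fibrous = 0, very_high = 0)
    structure(pct, class = "phenotype_summary", design = nms[i],
              t_eval = 0.6)
  })
  names(summaries) <- nms
  structure(list(
    metrics = data.frame(name = nms, N_V = N_V),
    summaries = summaries,
    deltas = NULL, reference = nms[1], failed = character(0), seed = 1L),
    class = "sweep_report")
}

# hand-built conformal mesh with explicit area weights
manual_mesh <- function(spec, areas, x = seq_along(areas), y = 0, z = 0) {
  n <- length(areas)
  df <- data.frame(id = seq_len(n), x = rep_len(x, n), y = rep_len(y, n),
                   z = rep_len(z, n), area = areas, junction = 0)
  attr(df, "spec") <- spec
  attr(df, "total_area") <- sum(areas)
  attr(df, "junctions") <- data.frame(x = numeric(0), y = numeric(0),
                                      z = numeric(0))
  attr(df, "junction_load") <- 0
  class(df) <- c("surface_mesh", "data.frame")
  df
}

subset_series <- function(fs, idx) {
  mesh0 <- fs$mesh
  mesh <- manual_mesh(attr(mesh0, "spec"), mesh0$area[idx],
                      x = mesh0$x[idx], y = mesh0$y[idx], z = mesh0$z[idx])
  mesh$id <- mesh0$id[idx]
  field_series(fs$values[idx, , drop = FALSE], fs$times, mesh, fs$field,
               fs$seed)
}
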