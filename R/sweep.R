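#' Scaling ratios frozen from a base design
#'
#' The dimensionless ratios that the porosity-preserving step-2 scaling
#' holds constant while the layer count changes: `h / D_strand`,
#' `Y / D_strand`, and the constraint that the strand count per layer
#' tracks the layer count (`N_H = N_V`).
#'
#' @param base a [scaffold_spec()].
#' @return An object of class `scaling_ratios`.
#' @export
scaling_ratios <- function(base) {
  stopifnot(is_scaffold_spec(base))
  structure(list(h_to_Dstrand = base$h / base$D_strand,
                 Y_to_Dstrand = base$Y / base$D_strand,
                 NH_equals_NV = TRUE),
            class = "scaling_ratios")
}

#' Step-1 design family: vary the strand count per layer
#'
#' Holds `N_V`, `D_strand` and `h` fixed and recomputes the horizontal span
#' `Y` for each strand count, producing the `S1-H{n}-V{N_V}` family (the
#' base design is reconstructed when its own `N_H` is in the range).
#'
#' @param base the reference design (a [scaffold_spec()]).
#' @param NH integer vector of strand counts per layer (each >= 2).
#' @return List of [scaffold_spec()] objects.
#' @examples
#' length(step1_designs(original_scaffold()))  # 5 designs, H6..H10
#' @export
step1_designs <- function(base, NH = 6:10) {
  stopifnot(is_scaffold_spec(base))
  if (any(NH < 2)) stop("'NH' values must be >= 2", call. = FALSE)
  lapply(NH, function(nh)
    scaffold_spec(N_H = nh, N_V = base$N_V, D_scaffold = base$D_scaffold,
                  H_scaffold = base$H_scaffold, D_strand = base$D_strand,
                  h = base$h, step = 1))
}

#' Step-2 design family: porosity-preserving scaling of the layer count
#'
#' Scales the base lattice while keeping the outer dimensions
#' (`D_scaffold`, `H_scaffold`) and — by construction — the porosity
#' nearly constant. The ratios `h/D_strand` and `Y/D_strand` are frozen
#' from the base and the layer stack must still tile the height,
#' `H_scaffold = N_V * h`, so each layer count `N_V` determines
#' `D_strand = H_scaffold / (N_V * h_to_Dstrand)`, then `h`, `Y` and
#' `D_pore`; the strand count per layer tracks the layer count
#' (`N_H = N_V`). Applying the rule at the base's own `N_V` reproduces the
#' base exactly.
#'
#' Variants whose strand diameter falls outside the direct-ink-writing
#' manufacturability bounds are excluded with a warning and listed in the
#' `excluded` attribute.
#'
#' @param base the step-1 selection (a [scaffold_spec()]).
#' @param NV integer vector of layer counts.
#' @param d_strand_bounds feasible strand-diameter range, mm; `NULL`
#'   disables the check.
#' @param ratios a [scaling_ratios()]; frozen from `base` by default.
#' @param step step label for the design names.
#' @return List of [scaffold_spec()] objects, with an `excluded` attribute
#'   (data frame of design name, D_strand and reason) when designs were
#'   dropped.
#' @examples
#' vapply(step2_designs(scaffold_spec(9, 9, step = 1)),
#'        function(s) s$name, "")
#' @export
step2_designs <- function(base, NV = c(8, 10, 11),
                          d_strand_bounds = c(0.5, 0.8),
                          ratios = scaling_ratios(base), step = 2) {
  stopifnot(is_scaffold_spec(base), inherits(ratios, "scaling_ratios"))
  specs <- list()
  excluded <- data.frame(name = character(0), D_strand = numeric(0),
                         reason = character(0))
  for (nv in NV) {
    D <- base$H_scaffold / (nv * ratios$h_to_Dstrand)
    nh <- if (isTRUE(ratios$NH_equals_NV)) nv else base$N_H
    nm <- sprintf("S%d-H%d-V%d", step, nh, nv)
    if (!is.null(d_strand_bounds) &&
        (D < d_strand_bounds[1] || D > d_strand_bounds[2])) {
      warning(sprintf(
        "%s excluded: D_strand = %.0f um outside DIW bounds [%.0f, %.0f] um",
        nm, 1000 * D, 1000 * d_strand_bounds[1], 1000 * d_strand_bounds[2]))
      excluded <- rbind(excluded, data.frame(
        name = nm, D_strand = D, reason = "D_strand outside DIW bounds"))
      next
    }
    specs[[length(specs) + 1L]] <- scaffold_spec(
      N_H = nh, N_V = nv, D_scaffold = base$D_scaffold,
      H_scaffold = base$H_scaffold, D_strand = D,
      Y = ratios$Y_to_Dstrand * D, h = ratios$h_to_Dstrand * D,
      step = step)
  }
  attr(specs, "excluded") <- excluded
  specs
}

#' Full-factorial extension of the two-step strategy
#'
#' Applies the step-2 variant rule (layer counts `N_V + offsets` with
#' ratios frozen per base) to every step-1 design, enumerating the design
#' space a full factorial sweep would have covered. Manufacturability
#' bounds are not applied here; the enumeration counts candidate
#' architectures.
#'
#' @param step1 list of step-1 designs ([scaffold_spec()] objects).
#' @param offsets layer-count offsets defining the variants per base.
#' @return List with `designs` (flat list of specs) and `count`.
#' @examples
#' enumerate_full_factorial(step1_designs(original_scaffold()))$count  # 15
#' @export
enumerate_full_factorial <- function(step1, offsets = c(-1, 1, 2)) {
  designs <- list()
  for (base in step1) {
    v <- step2_designs(base, NV = base$N_V + offsets,
                       d_strand_bounds = NULL, step = 2)
    designs <- c(designs, v)
  }
  list(designs = designs, count = length(designs))
}

#' Run the design sweep pipeline
#'
#' For each design: compute pore metrics, generate the synthetic cycle,
#' average the fields into the stimulus time series, locate `S_Max1` /
#' `S_Max2`, classify the surface phenotype map at the `S_Max2` time and
#' summarise it, then difference every summary against the reference
#' design. A failing design is recorded and the sweep continues.
#'
#' @param designs list of [scaffold_spec()] objects.
#' @param protocol a [loading_protocol()] (heights are taken per design).
#' @param fluid a [fluid_properties()].
#' @param params a [surrogate_params()].
#' @param consts a [stimulus_constants()].
#' @param reference index or name of the reference design (default the
#'   first).
#' @param n_nodes surface nodes per design.
#' @param seed base RNG seed; design `i` uses `seed + i - 1`.
#' @return An object of class `sweep_report`: list with `metrics` (one row
#'   per design: porosity, `D_pore`, peak averages, `S_Max1/2`), `series`,
#'   `summaries`, `deltas`, `reference`, `failed`, `seed`.
#' @export
run_sweep <- function(designs, protocol = NULL, fluid = fluid_properties(),
                      params = default_surrogate_params(),
                      consts = stimulus_constants(), reference = 1L,
                      n_nodes = 5000, seed = 1L) {
  stopifnot(length(designs) >= 1)
  names(designs) <- vapply(designs, function(s) s$name, "")
  rows <- list(); summaries <- list(); series <- list()
  failed <- character(0)
  for (i in seq_along(designs)) {
    spec <- designs[[i]]
    res <- tryCatch({
      pr <- if (is.null(protocol))
        loading_protocol(scaffold_height = spec$H_scaffold)
      else protocol
      metrics <- pore_metrics(build_layout(spec))
      cyc <- generate_cycle(spec, pr, fluid, params, n_nodes = n_nodes,
                            seed = seed + i - 1L,
                            porosity = metrics$porosity)
      ser <- averaged_series(cyc$strain, cyc$wss, consts)
      sm <- find_smax(ser)
      map <- phenotype_map(cyc$strain, cyc$wss, sm$smax2[["time"]], consts)
      summ <- phenotype_percentages(map, cyc$mesh$area, design = spec$name,
                                    t_eval = sm$smax2[["time"]])
      shares <- contribution_shares(
        ser$oss_avg[ser$time == sm$smax2[["time"]]],
        ser$wss_avg[ser$time == sm$smax2[["time"]]], consts)
      list(row = data.frame(
        name = spec$name, N_H = spec$N_H, N_V = spec$N_V,
        D_strand = spec$D_strand, porosity = metrics$porosity,
        D_pore = metrics$D_pore,
        peak_oss = max(ser$oss_avg), peak_wss = max(ser$wss_avg),
        smax1 = sm$smax1[["value"]], t_smax1 = sm$smax1[["time"]],
        smax2 = sm$smax2[["value"]], t_smax2 = sm$smax2[["time"]],
        oss_share = shares[["oss"]], wss_share = shares[["wss"]]),
        summary = summ, series = ser)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, stats::setNames(conditionMessage(res), spec$name))
      next
    }
    rows[[spec$name]] <- res$row
    summaries[[spec$name]] <- res$summary
    series[[spec$name]] <- res$series
  }
  if (length(rows) == 0) stop("all designs failed", call. = FALSE)
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  ref_name <- if (is.numeric(reference)) names(designs)[reference]
  else reference
  if (!ref_name %in% names(summaries))
    stop(sprintf("reference design '%s' is not in the report", ref_name),
         call. = FALSE)
  deltas <- t(vapply(summaries, function(s)
    compare_designs(s, summaries[[ref_name]]),
    numeric(length(PHENOTYPE_LEVELS))))
  structure(
    list(metrics = metrics, summaries = summaries, series = series,
         deltas = deltas, reference = ref_name, failed = failed,
         seed = seed),
    class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("Design sweep: %d design(s), reference '%s'\n",
              nrow(x$metrics), x$reference))
  df <- x$metrics
  df$porosity <- sprintf("%.1f%%", 100 * df$porosity)
  df$D_pore <- sprintf("%.0f um", df$D_pore)
  print(df[, c("name", "porosity", "D_pore", "peak_oss", "peak_wss",
               "smax2", "wss_share")], digits = 3, row.names = FALSE)
  if (length(x$failed))
    cat("failed:", paste(names(x$failed), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sweep_report <- function(object, ...) {
  pct <- t(vapply(object$summaries, unclass,
                  numeric(length(PHENOTYPE_LEVELS))))
  cat("Phenotype surface shares (%):\n")
  print(round(pct, 2))
  cat(sprintf("\nDeltas vs reference '%s' (percentage points):\n",
              object$reference))
  print(round(object$deltas, 2))
  invisible(list(percentages = pct, deltas = object$deltas))
}

#' Select the best design under a stopping rule
#'
#' Picks the design maximising the surface share of the target phenotype.
#' Designs whose criterion lies within `stop_threshold` percentage points
#' of the maximum are treated as tied — an improvement that small is
#' considered insignificant and recorded as a stopping decision — and the
#' tie breaks toward the fewest vertical layers (cheapest manufacture),
#' then sweep order.
#'
#' @param report a [run_sweep()] result.
#' @param criterion phenotype class to maximise (default `"cartilage"`).
#' @param stop_threshold insignificance band, percentage points.
#' @return List with `name`, `value` (criterion %), `stopped` (logical:
#'   was the final improvement below the threshold?) and `trace` (per
#'   design: criterion value, delta to the running best, tied flag).
#' @export
select_best <- function(report, criterion = "cartilage",
                        stop_threshold = 1) {
  stopifnot(inherits(report, "sweep_report"))
  if (!criterion %in% PHENOTYPE_LEVELS)
    stop(sprintf("unknown criterion '%s'", criterion), call. = FALSE)
  vals <- vapply(report$summaries, function(s) unclass(s)[[criterion]],
                 numeric(1))
  if (length(vals) == 0) stop("empty report", call. = FALSE)
  best <- max(vals)
  tied <- vals > best - stop_threshold
  nv <- report$metrics$N_V[match(names(vals), report$metrics$name)]
  cand <- which(tied)
  sel <- cand[order(nv[cand], cand)][1]
  trace <- data.frame(name = names(vals), criterion = vals,
                      delta_to_best = vals - best, tied = tied,
                      row.names = NULL)
  list(name = names(vals)[sel], value = vals[[sel]],
       stopped = sum(tied) > 1, trace = trace)
}
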