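#' Mechanoregulation stimulus constants
#'
#' Scaling constants of the biphasic stimulus `S = OSS/a + WSS/b`:
#' `a = 0.0375` (dimensionless strain scale) and `b = 10` mPa (fluid shear
#' scale).
#'
#' @param a strain scale (> 0).
#' @param b shear-stress scale, mPa (> 0).
#' @return An object of class `stimulus_constants`.
#' @export
stimulus_constants <- function(a = 0.0375, b = 10) {
  stopifnot_scalar(a, "a", positive = TRUE)
  stopifnot_scalar(b, "b", positive = TRUE)
  structure(list(a = a, b = b), class = "stimulus_constants")
}

#' Biphasic mechanoregulation stimulus
#'
#' `S = OSS/a + WSS/b`: octahedral shear strain of the solid phase plus
#' wall shear stress of the fluid phase, each scaled by its constant.
#' Linear in both arguments.
#'
#' @param oss octahedral shear strain (dimensionless, >= 0); vectorised.
#' @param wss wall shear stress, mPa (>= 0); vectorised.
#' @param consts a [stimulus_constants()].
#' @return Stimulus value(s) `S`.
#' @examples
#' stimulus(0.0375, 10)  # both terms contribute 1
#' @export
stimulus <- function(oss, wss, consts = stimulus_constants()) {
  stopifnot(inherits(consts, "stimulus_constants"))
  if (any(oss < 0, na.rm = TRUE) || any(wss < 0, na.rm = TRUE))
    stop("'oss' and 'wss' must be >= 0", call. = FALSE)
  oss / consts$a + wss / consts$b
}

PHENOTYPE_LEVELS <- c("very_low", "bone", "cartilage", "fibrous", "very_high")
PHENOTYPE_BREAKS <- c(-Inf, 0.01, 1, 3, 6, Inf)

#' Predicted tissue phenotype from the stimulus value
#'
#' Partition of the stimulus axis with inclusive upper bounds:
#' `S <= 0.01` very low stimuli, `0.01 < S <= 1` bone, `1 < S <= 3`
#' cartilage, `3 < S <= 6` fibrous, `S > 6` very high stimuli.
#'
#' @param S stimulus value(s); finite.
#' @return Factor with levels `very_low, bone, cartilage, fibrous,
#'   very_high`.
#' @examples
#' classify_phenotype(c(0.005, 1, 1 + 1e-9, 6.5))
#' @export
classify_phenotype <- function(S) {
  if (any(!is.finite(S)))
    stop("classification error: stimulus values must be finite",
         call. = FALSE)
  cut(S, breaks = PHENOTYPE_BREAKS, labels = PHENOTYPE_LEVELS, right = TRUE)
}

#' @rdname classify_phenotype
#' @export
phenotype_levels <- function() PHENOTYPE_LEVELS

#' Match conformal node sets
#'
#' Pairs each solid-phase (FE) surface node with the fluid-phase (CFD)
#' node at the same position, the conformal-interface contract that lets
#' OSS and WSS be combined per node. When the two tables share identical
#' ids and coordinates the mapping is the identity; otherwise nodes are
#' paired by sorted position and every pair must agree within `tolerance`.
#'
#' @param fe_nodes,cfd_nodes data frames with columns `id, x, y, z`.
#' @param tolerance maximum coordinate distance for a match, mm.
#' @return Data frame with columns `fe_id`, `cfd_id`.
#' @export
match_nodes <- function(fe_nodes, cfd_nodes, tolerance = 1e-6) {
  for (nm in c("id", "x", "y", "z")) {
    if (is.null(fe_nodes[[nm]]) || is.null(cfd_nodes[[nm]]))
      stop(sprintf("node tables need a '%s' column", nm), call. = FALSE)
  }
  if (nrow(fe_nodes) == 0 || nrow(cfd_nodes) == 0)
    stop("node sets must be non-empty", call. = FALSE)
  if (nrow(fe_nodes) != nrow(cfd_nodes)) {
    extra <- if (nrow(fe_nodes) > nrow(cfd_nodes))
      setdiff(fe_nodes$id, cfd_nodes$id) else setdiff(cfd_nodes$id, fe_nodes$id)
    stop(sprintf("conformality error: unmatched node(s) %s",
                 paste(utils::head(extra, 5), collapse = ", ")),
         call. = FALSE)
  }
  of <- order(fe_nodes$x, fe_nodes$y, fe_nodes$z)
  oc <- order(cfd_nodes$x, cfd_nodes$y, cfd_nodes$z)
  d <- sqrt((fe_nodes$x[of] - cfd_nodes$x[oc])^2 +
              (fe_nodes$y[of] - cfd_nodes$y[oc])^2 +
              (fe_nodes$z[of] - cfd_nodes$z[oc])^2)
  bad <- d > tolerance
  if (any(bad))
    stop(sprintf("conformality error: unmatched node(s) %s",
                 paste(utils::head(fe_nodes$id[of][bad], 5), collapse = ", ")),
         call. = FALSE)
  data.frame(fe_id = fe_nodes$id[of], cfd_id = cfd_nodes$id[oc])
}

check_conformal <- function(strain, wss) {
  stopifnot(inherits(strain, "field_series"), inherits(wss, "field_series"))
  if (!identical(strain$mesh$id, wss$mesh$id))
    stop("conformality error: strain and WSS series have different node sets",
         call. = FALSE)
  if (!isTRUE(all.equal(strain$mesh$area, wss$mesh$area)))
    stop("conformality error: area weights differ between series",
         call. = FALSE)
  if (!isTRUE(all.equal(strain$times, wss$times)))
    stop("time grids of the strain and WSS series differ", call. = FALSE)
  invisible(TRUE)
}

#' Surface-averaged stimulus time series
#'
#' At every time point: `OSS_avg` is the arithmetic mean of the nodal
#' octahedral shear strain over all surface nodes, `WSS_avg` the
#' area-weighted mean of the nodal wall shear stress over the scaffold
#' surface, and `S_avg` the stimulus of the two averages,
#' `S_avg = OSS_avg/a + WSS_avg/b`.
#'
#' @param strain,wss conformal [field_series()] objects (`oss`, `wss`).
#' @param consts a [stimulus_constants()].
#' @return A data frame of class `stimulus_series` with columns `time`,
#'   `oss_avg`, `wss_avg`, `s_avg`; the design name and `consts` are
#'   attached as attributes.
#' @export
averaged_series <- function(strain, wss, consts = stimulus_constants()) {
  check_conformal(strain, wss)
  oss_avg <- colMeans(strain$values)
  w <- wss$mesh$area
  wss_avg <- as.vector(crossprod(wss$values, w)) / sum(w)
  out <- data.frame(time = strain$times, oss_avg = oss_avg,
                    wss_avg = wss_avg,
                    s_avg = stimulus(oss_avg, wss_avg, consts))
  attr(out, "design") <- strain$design
  attr(out, "consts") <- consts
  class(out) <- c("stimulus_series", "data.frame")
  out
}

#' Stimulus maxima of the compression and release half-cycles
#'
#' `S_Max1` is the maximum of `S_avg` while the piston moves down
#' (`0 <= t < T/2`), `S_Max2` the maximum during the release phase
#' (`T/2 <= t < T`). Ties within a window break toward the later time, so
#' a time-symmetric series still reports its release-phase maximum as
#' `S_Max2`.
#'
#' @param series a [averaged_series()] result (or any data frame with
#'   `time` and `s_avg`).
#' @param period cycle period, s; inferred from the time grid when `NULL`.
#' @return List with `smax1` and `smax2`, each `c(value =, time =)`.
#' @export
find_smax <- function(series, period = NULL) {
  t <- series$time
  s <- series$s_avg
  if (length(t) < 2) stop("series shorter than one cycle", call. = FALSE)
  dt <- stats::median(diff(t))
  if (is.null(period)) {
    # grids either include both cycle ends (0..T) or stop at T - dt
    period <- if (any(abs(t - max(t) / 2) < 1e-9)) max(t) else max(t) + dt
  }
  if (max(t) < period - dt - 1e-9)
    stop("series shorter than one cycle", call. = FALSE)
  half <- period / 2
  pick <- function(win) {
    if (!any(win)) stop("series does not cover both half-cycles",
                        call. = FALSE)
    sv <- s[win]; tv <- t[win]
    idx <- max(which(sv == max(sv)))       # tie -> later time
    c(value = sv[idx], time = tv[idx])
  }
  list(smax1 = pick(t >= 0 & t < half),
       smax2 = pick(t >= half & t < period))
}

#' Per-node phenotype map at an evaluation time
#'
#' Computes the nodal stimulus `S = OSS/a + WSS/b` at `t_eval` (normally
#' the `S_Max2` time, when the surface-averaged stimulus peaks during the
#' release phase) and classifies every node.
#'
#' @param strain,wss conformal [field_series()] objects.
#' @param t_eval evaluation time; must be on the series time grid.
#' @param consts a [stimulus_constants()].
#' @return Data frame with `node_id`, `S`, `class`.
#' @export
phenotype_map <- function(strain, wss, t_eval,
                          consts = stimulus_constants()) {
  check_conformal(strain, wss)
  j <- which(abs(strain$times - t_eval) < 1e-9)
  if (length(j) != 1)
    stop(sprintf("t_eval = %g s is not on the series time grid", t_eval),
         call. = FALSE)
  S <- stimulus(strain$values[, j], wss$values[, j], consts)
  data.frame(node_id = strain$mesh$id, S = S, class = classify_phenotype(S))
}

#' Surface-area percentage per predicted phenotype
#'
#' @param map a [phenotype_map()] result (or any data frame with a `class`
#'   column).
#' @param areas per-node area weights, mm^2 (> 0), aligned with `map`.
#' @param design,t_eval optional metadata stored on the result.
#' @return Named numeric vector of class `phenotype_summary` (one
#'   percentage per phenotype class, summing to 100).
#' @export
phenotype_percentages <- function(map, areas, design = NA_character_,
                                  t_eval = NA_real_) {
  if (length(areas) != nrow(map))
    stop("'areas' must have one weight per node", call. = FALSE)
  if (any(areas <= 0)) stop("'areas' must be > 0", call. = FALSE)
  cls <- factor(map$class, levels = PHENOTYPE_LEVELS)
  by_class <- vapply(split(areas, cls), sum, numeric(1))
  pct <- 100 * by_class / sum(areas)
  structure(pct, class = "phenotype_summary", design = design,
            t_eval = t_eval)
}

#' @export
print.phenotype_summary <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("Predicted phenotype surface shares%s%s\n",
              if (!is.na(d)) paste0(" for '", d, "'") else "",
              if (!is.na(attr(x, "t_eval")))
                sprintf(" at t = %g s", attr(x, "t_eval")) else ""))
  v <- unclass(x)
  attributes(v) <- list(names = names(x))
  print(round(v, 2))
  invisible(x)
}

#' Phenotype-share differences between two designs
#'
#' Per-class difference in surface percentage (candidate minus reference),
#' in percentage points. The deltas sum to zero.
#'
#' @param summary,reference [phenotype_percentages()] results over the same
#'   class set.
#' @return Named numeric vector of deltas.
#' @export
compare_designs <- function(summary, reference) {
  if (!identical(names(summary), names(reference)))
    stop("summaries cover different class sets", call. = FALSE)
  out <- unclass(summary) - unclass(reference)
  attributes(out) <- list(names = names(summary))
  out
}

#' Relative OSS and WSS contributions to the stimulus
#'
#' Shares of the solid-strain and fluid-shear terms in
#' `S = OSS/a + WSS/b`, in percent.
#'
#' @param oss_avg,wss_avg surface-averaged OSS and WSS (mPa) at the time of
#'   interest; not both zero.
#' @param consts a [stimulus_constants()].
#' @return `c(oss = , wss = )` in percent, summing to 100.
#' @export
contribution_shares <- function(oss_avg, wss_avg,
                                consts = stimulus_constants()) {
  S <- stimulus(oss_avg, wss_avg, consts)
  if (S == 0)
    stop("undefined shares: total stimulus is zero", call. = FALSE)
  c(oss = 100 * (oss_avg / consts$a) / S,
    wss = 100 * (wss_avg / consts$b) / S)
}
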