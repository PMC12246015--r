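# JSON / CSV report writers

#' Write a phenotype map and summary to disk
#'
#' `write_phenotype_map()` writes the per-node stimulus and class table as
#' CSV (with provenance header); `write_summary_json()` writes a
#' [phenotype_percentages()] summary as JSON.
#'
#' @param map a [phenotype_map()] result.
#' @param summary a [phenotype_percentages()] result.
#' @param path output file path.
#' @param config_hash optional provenance hash.
#' @param overwrite overwrite an existing file?
#' @return The path, invisibly.
#' @export
write_phenotype_map <- function(map, path, config_hash = NA_character_,
                                overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop(sprintf("'%s' exists; set overwrite = TRUE to replace it", path),
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# scaffoldmech phenotype map schema 1.0",
               sprintf("# config_hash: %s", config_hash)), con)
  utils::write.table(map, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_map
#' @export
write_summary_json <- function(summary, path, config_hash = NA_character_,
                               overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop(sprintf("'%s' exists; set overwrite = TRUE to replace it", path),
         call. = FALSE)
  obj <- list(schema = "scaffoldmech phenotype summary 1.0",
              design = attr(summary, "design"),
              t_eval_s = attr(summary, "t_eval"),
              percentages = as.list(unclass(summary)),
              config_hash = config_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a sweep report to disk
#'
#' Emits a JSON report (per-design metrics, phenotype percentages, deltas
#' against the reference, selection trace) plus a flat CSV of the
#' per-design metrics.
#'
#' @param report a [run_sweep()] result.
#' @param dir output directory (created if needed).
#' @param selection optional [select_best()] result to embed.
#' @param config_hash optional provenance hash.
#' @param overwrite overwrite existing files?
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sweep_report <- function(report, dir, selection = NULL,
                               config_hash = NA_character_,
                               overwrite = FALSE) {
  stopifnot(inherits(report, "sweep_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "sweep-report.json")
  csv_path <- file.path(dir, "sweep-metrics.csv")
  for (p in c(json_path, csv_path))
    if (file.exists(p) && !overwrite)
      stop(sprintf("'%s' exists; set overwrite = TRUE to replace it", p),
           call. = FALSE)
  obj <- list(
    schema = "scaffoldmech sweep report 1.0",
    reference = report$reference,
    seed = report$seed,
    metrics = report$metrics,
    percentages = lapply(report$summaries, function(s)
      as.list(unclass(s))),
    deltas_vs_reference = apply(report$deltas, 1, as.list),
    failed = as.list(report$failed),
    selection = if (!is.null(selection))
      selection[c("name", "value", "stopped")],
    config_hash = config_hash)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  utils::write.csv(report$metrics, csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
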