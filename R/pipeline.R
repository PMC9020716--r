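# End-to-end runs: read -> filter -> log2 -> impute -> enrich, and the
# FRAP fitting pipeline, with result tables and a run log written to an
# output directory.  A run is driven by a single config (a YAML file or
# an R list); identical config + seed reproduces identical tables.

#' Read a run configuration
#'
#' @param config A YAML file path or a named list.
#' @return The config as a named list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

default_or <- function(x, default) if (is.null(x)) default else x

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

write_tsv <- function(df, path, provenance = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (line in provenance) writeLines(paste0("# ", line), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full proximity-interactor enrichment pipeline
#'
#' Executes read -> filter -> log2 transform -> impute -> enrich and
#' writes the enrichment table, significant-interactor list, volcano and
#' MA tables, filter report and a run log into the output directory.
#' When both imputation methods are requested, both result sets are
#' written along with a per-protein comparison table of the two log2
#' fold changes and significance calls.
#'
#' Config keys (YAML or list): `protein_groups` and `design` (paths),
#' `output_dir`, `imputation` (`"lod"`, `"nd"`, or both), `seed`,
#' optional blocks `filters` (`min_razor`, `min_group_values`,
#' `group_value_mode`), `nd` (`shift`, `width`), `thresholds`
#' (`min_log2_fc`, `max_p`), and `column_map` overrides.
#'
#' @param config YAML path or named list.
#' @return Invisibly, a list per imputation method with the in-memory
#'   `enrichment_table`, the `significant` id vector, plus `report` and
#'   the output `paths`.
#' @export
run_enrichment <- function(config) {
  cfg <- read_run_config(config)
  for (key in c("protein_groups", "design", "output_dir"))
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  methods <- default_or(cfg$imputation, "lod")
  stopifnot(all(methods %in% c("lod", "nd")))
  seed <- as.integer(default_or(cfg$seed, 1L))

  cmap <- utils::modifyList(default_column_map(),
                            default_or(cfg$column_map, list()))
  design <- run_stage("read-design", read_design(cfg$design))
  table <- run_stage("read-protein-groups",
                     read_protein_groups(cfg$protein_groups, design, cmap))

  f <- default_or(cfg$filters, list())
  filtered <- run_stage("filter", apply_filters(
    table,
    min_razor = default_or(f$min_razor, 2),
    min_group_values = default_or(f$min_group_values, 2),
    group_value_mode = default_or(f$group_value_mode, "any_group")))

  logmat <- run_stage("log-transform", log_transform(filtered$table))

  th <- default_or(cfg$thresholds, list())
  thresholds <- enrichment_thresholds(
    min_log2_fc = default_or(th$min_log2_fc, 1),
    max_p = default_or(th$max_p, 0.05))

  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  provenance <- c(
    paste0("proxitome enrichment run; seed: ", seed),
    paste0("thresholds: log2_fc > ", thresholds$min_log2_fc,
           ", p < ", thresholds$max_p),
    paste0("filters: min_razor ", default_or(f$min_razor, 2),
           ", min_group_values ", default_or(f$min_group_values, 2),
           ", mode ", default_or(f$group_value_mode, "any_group")))

  results <- list()
  log_lines <- c(provenance,
                 paste0("input: ", cfg$protein_groups),
                 paste0("filter report: ",
                        filtered$report$n_input, " in, ",
                        filtered$report$n_retained, " retained"))
  for (method in methods) {
    imputed <- run_stage(paste0("impute-", method),
      if (method == "lod") impute_lod(logmat)
      else impute_nd(logmat, nd_params(
        shift = default_or(cfg$nd$shift, 1.8),
        width = default_or(cfg$nd$width, 0.3),
        seed = seed)))
    enr <- run_stage("enrich",
                     compute_enrichment(imputed, thresholds))
    sig <- significant_set(enr)
    prov <- c(provenance, paste0("imputation: ", method))
    paths <- c(
      enrichment = file.path(out_dir,
                             paste0("enrichment_", method, ".tsv")),
      significant = file.path(out_dir,
                              paste0("significant_", method, ".txt")),
      volcano = file.path(out_dir, paste0("volcano_", method, ".tsv")),
      ma = file.path(out_dir, paste0("ma_", method, ".tsv")))
    write_tsv(as.data.frame(enr), paths["enrichment"], prov)
    writeLines(sig, paths["significant"])
    write_tsv(volcano_table(enr), paths["volcano"], prov)
    write_tsv(ma_table(enr), paths["ma"], prov)
    log_lines <- c(log_lines,
                   paste0(method, ": ", length(sig),
                          " significant interactors"))
    results[[method]] <- list(enrichment = enr, significant = sig,
                              report = filtered$report, paths = paths)
  }

  report_path <- file.path(out_dir, "filter_report.tsv")
  write_tsv(filter_report_table(filtered$report), report_path, provenance)

  if (all(c("lod", "nd") %in% methods)) {
    cmp <- merge(
      results$lod$enrichment[, c("group_id", "log2_fc", "p_value",
                                 "significant")],
      results$nd$enrichment[, c("group_id", "log2_fc", "p_value",
                                "significant")],
      by = "group_id", suffixes = c("_lod", "_nd"))
    cmp$inverted <- sign(cmp$log2_fc_lod) != sign(cmp$log2_fc_nd)
    cmp_path <- file.path(out_dir, "imputation_comparison.tsv")
    write_tsv(cmp, cmp_path, provenance)
    results$comparison <- cmp
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

#' Read FRAP traces from a delimited table
#'
#' The file holds columns `time_s` and `intensity`, plus optionally
#' `trace_id` when several traces share the file.
#'
#' @param path Tab- or comma-separated file.
#' @param bleach_index 1-based index of the first post-bleach point
#'   (applies to every trace in the file).
#' @return List of raw `frap_trace` objects.
#' @export
read_frap_traces <- function(path, bleach_index) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(d) == 0) stop("trace file is empty: ", path)
  if (!all(c("time_s", "intensity") %in% names(d)))
    stop("trace file needs columns 'time_s' and 'intensity'")
  groups <- if ("trace_id" %in% names(d))
    split(d, d$trace_id) else list(trace = d)
  lapply(groups, function(g)
    frap_trace(g$time_s, g$intensity, bleach_index))
}

#' Run the FRAP quantification pipeline
#'
#' Normalizes each trace to its pre-bleach mean, fits the
#' single-exponential recovery model per trace, and writes a per-trace
#' fit table plus an ensemble summary (mean and SD of mobile fraction
#' and half-time).
#'
#' Config keys: `traces` (path to a trace table, see
#' [read_frap_traces()]), `bleach_index`, `output_dir`, optional
#' `n_prebleach`.
#'
#' @param config YAML path or named list.
#' @return Invisibly, the result of [fit_recovery_ensemble()] plus
#'   output `paths`.
#' @export
run_frap <- function(config) {
  cfg <- read_run_config(config)
  for (key in c("traces", "bleach_index", "output_dir"))
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  traces <- run_stage("read-traces",
                      read_frap_traces(cfg$traces, cfg$bleach_index))
  normalized <- run_stage("normalize",
    lapply(traces, normalize_trace,
           n_prebleach = cfg$n_prebleach))
  res <- run_stage("fit", fit_recovery_ensemble(normalized))

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- paste0("proxitome FRAP run; bleach_index: ", cfg$bleach_index)
  paths <- c(fits = file.path(cfg$output_dir, "recovery_fits.tsv"),
             summary = file.path(cfg$output_dir, "recovery_summary.tsv"))
  res$fits$trace <- names(traces)
  write_tsv(res$fits, paths["fits"], prov)
  write_tsv(res$summary, paths["summary"], prov)
  res$paths <- paths
  invisible(res)
}
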