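# End-to-end pipeline runner and command entry points.
#
# The analysis flow mirrors the emulated study: per-ROI tumor boundary ->
# TC/TF/PT partition -> per-phenotype densities -> macrophage subtype
# profile -> immunotype calls -> Wilcoxon comparison battery. All outputs
# are tidy delimited text; every run writes a provenance record (config,
# package version, seed) beside its outputs.

#' Pipeline configuration
#'
#' @param band_width Invasive-front band width in micrometres (default 150).
#' @param grid_resolution Raster cell size for boundary estimation and
#'   region-area computation (um, default 5).
#' @param closing_radius Morphological closing radius (um, default 30).
#' @param pooling Density pooling rule across ROIs: `"pooled"` (sum counts /
#'   sum areas, default) or `"roi_mean"`.
#' @param no_tumor_policy ROI without tumor cells: `"error"` (default) or
#'   `"all_pt"`.
#' @param immunotype_threshold CD8 density cutoff (cells/mm^2) for the
#'   immunotype rule; `NULL` (default) uses the cohort median CD8 TC density.
#' @param alpha Significance level (default 0.05).
#' @param fdr Add a Benjamini-Hochberg column to the battery?
#' @param strict Stop on the first per-lesion failure instead of skipping
#'   the lesion with a warning?
#' @param seed Seed recorded in provenance (the analysis itself is
#'   deterministic; the seed matters when the input cohort is simulated).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(band_width = 150, grid_resolution = 5,
                            closing_radius = 30,
                            pooling = c("pooled", "roi_mean"),
                            no_tumor_policy = c("error", "all_pt"),
                            immunotype_threshold = NULL,
                            alpha = 0.05, fdr = FALSE, strict = FALSE,
                            seed = 1L) {
  pooling <- match.arg(pooling)
  no_tumor_policy <- match.arg(no_tumor_policy)
  stopifnot(band_width >= 0, grid_resolution > 0, closing_radius >= 0,
            alpha > 0, alpha < 1)
  if (!is.null(immunotype_threshold)) stopifnot(immunotype_threshold > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys raise an error naming the offending key, so typos fail fast.
#'
#' @param path YAML file; keys are the arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path) %||% list()
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, vals)
}

#' Read a synthetic-cohort configuration from a YAML file
#'
#' Scalar keys are the arguments of [synth_config()]; the nested
#' `intensities` block is a marker -> lesion_type -> region map of
#' cells/mm^2 values overriding the defaults. Unknown keys raise an error
#' naming the key.
#'
#' @param path YAML file.
#' @return A [synth_config()].
#' @export
read_synth_config <- function(path) {
  vals <- yaml::read_yaml(path) %||% list()
  unknown <- setdiff(names(vals), names(formals(synth_config)))
  if (length(unknown))
    stop("unknown config key: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(vals$intensities) && !is.data.frame(vals$intensities)) {
    tab <- default_intensities()
    for (m in names(vals$intensities))
      for (lt in names(vals$intensities[[m]]))
        for (rg in names(vals$intensities[[m]][[lt]])) {
          sel <- tab$marker == m & tab$lesion_type == lt & tab$region == rg
          if (!any(sel))
            stop("unknown intensity key: ", m, "/", lt, "/", rg, call. = FALSE)
          tab$lambda[sel] <- vals$intensities[[m]][[lt]][[rg]]
        }
    vals$intensities <- tab
  }
  do.call(synth_config, vals)
}

#' Run the full analysis on a cohort of sample maps
#'
#' @param samples List of [sample_map()] objects (one per lesion).
#' @param clinical Optional clinical table for the subgroup family.
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_result`: `densities` (single-marker
#'   phenotypes), `macrophages` (subtype densities), `heatmap` (median
#'   subtype matrix), `immunotypes`, `battery`, `immunotype_contrasts`
#'   (CD163 across immunotypes in TF and TC), `partitions`, and `log`
#'   (per-lesion failures, if any).
#' @export
run_pipeline <- function(samples, clinical = NULL, config = pipeline_config()) {
  stopifnot(length(samples) >= 1)
  dens <- list(); macs <- list(); parts <- list(); log <- character(0)
  for (s in samples) {
    key <- paste(s$patient_id, s$lesion_type, sep = ".")
    res <- tryCatch({
      b <- estimate_boundaries(s, config$grid_resolution, config$closing_radius,
                               config$no_tumor_policy)
      part <- assign_regions(s, b, config$band_width, config$grid_resolution)
      list(part = part,
           d = compute_densities(s, part, pooling = config$pooling),
           m = macrophage_profile(s, part, pooling = config$pooling))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- paste0(key, ": ", conditionMessage(res))
      if (config$strict) stop("lesion ", msg, call. = FALSE)
      warning("skipping lesion ", msg, call. = FALSE)
      log <- c(log, msg)
      next
    }
    parts[[key]] <- res$part
    dens[[key]] <- res$d
    macs[[key]] <- res$m
  }
  if (!length(dens)) stop("no lesion could be analyzed", call. = FALSE)
  densities <- do.call(rbind, dens)
  macrophages <- do.call(rbind, macs)
  rownames(densities) <- rownames(macrophages) <- NULL

  calls <- immunotype_calls(densities, threshold = config$immunotype_threshold)
  battery <- run_comparison_battery(rbind(densities, macrophages), clinical,
                                    alpha = config$alpha, fdr = config$fdr)
  itc <- rbind(
    compare_marker_across_immunotypes(densities, calls, "CD163", "TF",
                                      config$alpha),
    compare_marker_across_immunotypes(densities, calls, "CD163", "TC",
                                      config$alpha))
  structure(list(densities = densities, macrophages = macrophages,
                 heatmap = subtype_heatmap_matrix(macrophages),
                 immunotypes = calls, battery = battery,
                 immunotype_contrasts = itc,
                 partitions = parts, log = log, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  nsig <- sum(x$battery$significant, na.rm = TRUE)
  cat(sprintf(paste0("<pipeline_result> %d lesions, %d density rows; ",
                     "battery: %d/%d comparisons significant at alpha = %g\n"),
              length(x$partitions), nrow(x$densities), nsig,
              nrow(x$battery), x$config$alpha))
  if (length(x$log)) cat("  skipped:", length(x$log), "lesion(s)\n")
  invisible(x)
}

write_tidy <- function(df, path) {
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Simulate a cohort and write it to a directory
#'
#' Thin command wrapper: reads the generator configuration (YAML, optional),
#' simulates the cohort and writes cell tables, clinical table and
#' ground-truth sidecars plus a provenance record.
#'
#' @param config_path Optional YAML for [synth_config()] keys.
#' @param out_dir Output directory.
#' @param seed Optional seed overriding the config file's.
#' @return The `synth_cohort`, invisibly.
#' @export
cmd_simulate <- function(config_path = NULL, out_dir, seed = NULL) {
  cfg <- if (is.null(config_path)) synth_config() else read_synth_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cohort <- simulate_cohort(cfg)
  write_cohort(cohort, out_dir)
  write_provenance(out_dir, list(command = "simulate", seed = cfg$seed,
                                 n_patients = cfg$n_patients))
  invisible(cohort)
}

#' Run the analysis on a cohort directory
#'
#' Reads the cohort written by [cmd_simulate()] (or any directory of cell
#' tables in the same dialect), runs [run_pipeline()] and writes the five
#' result tables: `densities.tsv`, `macrophages.tsv`, `heatmap.tsv`,
#' `immunotypes.tsv`, `battery.tsv` (plus `immunotype_contrasts.tsv` and a
#' provenance record).
#'
#' @param cohort_dir Input cohort directory.
#' @param out_dir Output directory.
#' @param config_path Optional YAML for [pipeline_config()] keys.
#' @return The `pipeline_result`, invisibly.
#' @export
cmd_run <- function(cohort_dir, out_dir, config_path = NULL) {
  cfg <- if (is.null(config_path)) pipeline_config()
         else read_pipeline_config(config_path)
  cohort <- read_cohort(cohort_dir)
  res <- run_pipeline(cohort$samples, cohort$clinical, cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tidy(res$densities, file.path(out_dir, "densities.tsv"))
  write_tidy(res$macrophages, file.path(out_dir, "macrophages.tsv"))
  hm <- data.frame(stratum = rownames(res$heatmap), res$heatmap,
                   check.names = FALSE)
  write_tidy(hm, file.path(out_dir, "heatmap.tsv"))
  write_tidy(res$immunotypes, file.path(out_dir, "immunotypes.tsv"))
  write_tidy(res$battery, file.path(out_dir, "battery.tsv"))
  write_tidy(res$immunotype_contrasts,
             file.path(out_dir, "immunotype_contrasts.tsv"))
  if (length(res$log))
    writeLines(res$log, file.path(out_dir, "run_log.txt"))
  write_provenance(out_dir, list(command = "run", seed = cfg$seed,
                                 band_width = cfg$band_width,
                                 grid_resolution = cfg$grid_resolution,
                                 closing_radius = cfg$closing_radius,
                                 pooling = cfg$pooling,
                                 alpha = cfg$alpha))
  invisible(res)
}

write_provenance <- function(dir, fields) {
  rec <- c(list(package = "immuneband",
                version = as.character(utils::packageVersion("immuneband"))),
           fields)
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "provenance.json"))
}
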