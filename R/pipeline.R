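# File-in/file-out pipeline stages. Each stage validates its inputs, logs
# the exact thresholds and seed in use, and stops (without partial output)
# on validation failure. A thin command-line front-end over these
# functions ships in inst/cli/otu-triage.R.

.log_params <- function(stage, config, keys) {
  message(sprintf("[%s] %s", stage,
                  paste(sprintf("%s=%s", keys,
                                vapply(config[keys], format, character(1))),
                        collapse = " ")))
}

#' Score histology observations to subscores and markers
#'
#' @param histology_csv Per-mouse histology CSV (see [read_histology()]).
#' @param out Output CSV of subscores, overall score and the five-marker
#'   panel.
#' @return Invisibly, the combined data frame written to `out`.
#' @export
run_score <- function(histology_csv, out) {
  obs <- read_histology(histology_csv)
  subs <- overall_score(obs)
  panel <- marker_panel(obs, subs)
  res <- cbind(subs, as.data.frame(panel)[setdiff(names(panel),
                                                  names(subs))])
  utils::write.csv(res, out, row.names = FALSE)
  message(sprintf("[score] %d mice -> %s", nrow(res), out))
  invisible(res)
}

.load_filtered <- function(table_path, metadata_path, config) {
  table <- read_abundance_table(table_path, metadata_path)
  filter_otus(table, config$min_percent, config$min_samples)
}

#' Differential-abundance stage
#'
#' @param table_path,metadata_path Abundance table and metadata files.
#' @param comparison Two group levels of `group_field`, fold change first
#'   over second.
#' @param out Output CSV mirroring per-comparison differential statistics
#'   (otu, log2FC, t, p, q, significant).
#' @param group_field Metadata column defining the groups.
#' @param config A [pipeline_config()].
#' @return Invisibly, the [differential_otus()] data frame.
#' @export
run_diffabund <- function(table_path, metadata_path, comparison, out,
                          group_field = "treatment",
                          config = pipeline_config()) {
  table <- .load_filtered(table_path, metadata_path, config)
  .log_params("diffabund", config,
              c("min_percent", "floor", "fc_min", "fdr_max"))
  res <- differential_otus(table, group_field, comparison,
                           fc_min = config$fc_min, fdr_max = config$fdr_max,
                           floor = config$floor)
  utils::write.csv(res, out, row.names = FALSE)
  invisible(res)
}

#' Ordination stage
#'
#' @param table_path,metadata_path Abundance table and metadata files.
#' @param out_coords Output CSV of sample coordinates (PC1..PCk).
#' @param out_eigen Optional output CSV of eigenvalues and explained
#'   fractions.
#' @param k Number of axes.
#' @param config A [pipeline_config()].
#' @return Invisibly, the `ordination_result`.
#' @export
run_ordinate <- function(table_path, metadata_path, out_coords,
                         out_eigen = NULL, k = 3L,
                         config = pipeline_config()) {
  table <- .load_filtered(table_path, metadata_path, config)
  .log_params("ordinate", config,
              c("min_percent", "jaccard_mode", "presence_threshold"))
  ord <- ordinate(table, k = k, mode = config$jaccard_mode,
                  presence_threshold = config$presence_threshold)
  coords <- data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE)
  utils::write.csv(coords, out_coords, row.names = FALSE)
  if (!is.null(out_eigen)) {
    utils::write.csv(
      data.frame(axis = colnames(ord$coordinates),
                 eigenvalue = ord$eigenvalues, explained = ord$explained),
      out_eigen, row.names = FALSE)
  }
  invisible(ord)
}

#' Candidate-triage stage
#'
#' @param table_path,metadata_path Abundance table and metadata files
#'   (DKO and non-DKO mice).
#' @param markers_path Marker panel CSV for the DKO mice.
#' @param out_records Output CSV of per-OTU triage records.
#' @param out_verdicts Optional output JSON of verdict groupings.
#' @param config A [pipeline_config()].
#' @return Invisibly, the `triage_result`.
#' @export
run_triage <- function(table_path, metadata_path, markers_path,
                       out_records, out_verdicts = NULL,
                       config = pipeline_config()) {
  table <- .load_filtered(table_path, metadata_path, config)
  panels <- read_marker_panel(markers_path)
  .log_params("triage", config,
              c("min_percent", "floor", "cured_max", "sick_min",
                "r_threshold", "fc_min", "fdr_max", "adjust_method"))
  tri <- triage_otus(table, panels, config)
  utils::write.csv(tri$records, out_records, row.names = FALSE)
  if (!is.null(out_verdicts)) {
    jsonlite::write_json(
      split(tri$records$otu_id, tri$records$verdict),
      out_verdicts, auto_unbox = FALSE)
  }
  invisible(tri)
}

#' Simulation stage
#'
#' @param out_dir Directory receiving abundance.tsv, metadata.csv,
#'   markers.csv and truth.json.
#' @param config A [pipeline_config()]; its seed drives the generator.
#' @param sim_config Optional [simulation_config()] overriding the
#'   defaults (its seed is taken from `config$seed` when unset).
#' @return Invisibly, the `synthetic_study`.
#' @export
run_simulate <- function(out_dir, config = pipeline_config(),
                         sim_config = NULL) {
  if (is.null(sim_config)) sim_config <- simulation_config()
  if (is.null(sim_config$seed)) sim_config$seed <- config$seed
  message(sprintf("[simulate] seed=%d concentration=%g -> %s",
                  sim_config$seed, sim_config$concentration, out_dir))
  invisible(make_study(sim_config, dir = out_dir))
}

#' Report stage: group-mean table and verdict groupings
#'
#' Assembles the study-style summary: per-group mean abundance per OTU
#' with a total-classified row (the shape of the published group-mean
#' table), the harmonized pathology correlation per OTU, and, when triage
#' records are supplied, the verdict groupings.
#'
#' @param table_path,metadata_path Abundance table and metadata files.
#' @param markers_path Optional marker panel CSV (enables the correlation
#'   column).
#' @param records_path Optional triage-records CSV from [run_triage()]
#'   (enables the verdict groupings).
#' @param out Output CSV of the summary table.
#' @param group_by Metadata field(s) defining the group columns.
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary data frame.
#' @export
run_report <- function(table_path, metadata_path, out,
                       markers_path = NULL, records_path = NULL,
                       group_by = "treatment",
                       config = pipeline_config()) {
  table <- .load_filtered(table_path, metadata_path, config)
  profiles <- group_means(table, group_by)
  summary <- data.frame(otu = otu_ids(table), stringsAsFactors = FALSE)
  for (g in names(profiles)) {
    summary[[g]] <- unname(profiles[[g]]$mean_abundance[summary$otu])
  }
  if (!is.null(markers_path)) {
    panels <- read_marker_panel(markers_path)
    dko_ids <- sample_ids(table)[table$samples$genotype == "DKO"]
    pan <- marker_correlation_panel(subset_table(table, samples = dko_ids),
                                    panels,
                                    method = config$correlation_method)
    summary$pathology_r <- pan$harmonized_mean_r[match(summary$otu,
                                                       pan$otu_id)]
  }
  totals <- c(otu = "Total abundance",
              lapply(profiles, total_classified))
  if (!is.null(summary$pathology_r)) totals$pathology_r <- NA_real_
  summary <- rbind(summary, as.data.frame(totals, check.names = FALSE))
  utils::write.csv(summary, out, row.names = FALSE)
  if (!is.null(records_path)) {
    rec <- utils::read.csv(records_path, stringsAsFactors = FALSE)
    message("[report] verdicts: ",
            paste(sprintf("%s=%d", names(table(rec$verdict)),
                          as.integer(table(rec$verdict))), collapse = " "))
  }
  invisible(summary)
}
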