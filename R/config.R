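# Single source of truth for the pipeline's thresholds. Every printed
# constant of the published workflow is a named key with that value as the
# default; YAML round-trips are lossless.

#' Pipeline configuration
#'
#' @param min_percent OTU inclusion threshold: abundance strictly greater
#'   than this (percent) in at least `min_samples` samples.
#' @param min_samples Minimum samples above `min_percent`.
#' @param floor Detection floor (percent) applied inside log and ratio
#'   computations; raw tables are never altered.
#' @param fc_min Minimum fold change for a differential call (ratio scale).
#' @param fdr_max Maximum BH q-value for a differential call.
#' @param cured_max Maximum overall score of a cured mouse.
#' @param sick_min Minimum overall score of a sick mouse.
#' @param r_threshold Moderate-correlation threshold for the consensus
#'   verdict.
#' @param core_fold_max,core_p_min,core_min_mean Core-microbiota rule:
#'   fold ratio strictly below `core_fold_max`, p strictly above
#'   `core_p_min`, mean at least `core_min_mean` percent in both groups.
#' @param adjust_method Multiplicity adjustment in the cured/sick screen.
#' @param adjust_family `"candidates"` or `"all"` (see
#'   [cured_sick_screen()]).
#' @param family_alpha Pairwise threshold defining the candidate family.
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param jaccard_mode `"quantitative"` or `"binary"`.
#' @param presence_threshold Presence call (percent) for binary Jaccard.
#' @param seed Integer seed for any stochastic step.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_percent = 0.5, min_samples = 1L,
                            floor = 0.1, fc_min = 1.2, fdr_max = 0.05,
                            cured_max = 1, sick_min = 5, r_threshold = 0.3,
                            core_fold_max = 2, core_p_min = 0.09,
                            core_min_mean = 0.2,
                            adjust_method = "bonferroni",
                            adjust_family = "candidates",
                            family_alpha = 0.05,
                            correlation_method = "pearson",
                            jaccard_mode = "quantitative",
                            presence_threshold = 0.5,
                            seed = 1L) {
  cfg <- list(min_percent = min_percent, min_samples = as.integer(min_samples),
              floor = floor, fc_min = fc_min, fdr_max = fdr_max,
              cured_max = cured_max, sick_min = sick_min,
              r_threshold = r_threshold, core_fold_max = core_fold_max,
              core_p_min = core_p_min, core_min_mean = core_min_mean,
              adjust_method = adjust_method, adjust_family = adjust_family,
              family_alpha = family_alpha,
              correlation_method = correlation_method,
              jaccard_mode = jaccard_mode,
              presence_threshold = presence_threshold,
              seed = as.integer(seed))
  num <- c("min_percent", "floor", "fc_min", "fdr_max", "cured_max",
           "sick_min", "r_threshold", "core_fold_max", "core_p_min",
           "core_min_mean", "family_alpha", "presence_threshold")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] < 0) {
      stop("config key '", k, "' must be a non-negative scalar")
    }
  }
  if (!cfg$adjust_method %in% c("bonferroni", "holm", "BH")) {
    stop("unknown adjust_method: ", cfg$adjust_method)
  }
  if (!cfg$adjust_family %in% c("candidates", "all")) {
    stop("unknown adjust_family: ", cfg$adjust_family)
  }
  if (!cfg$correlation_method %in% c("pearson", "spearman")) {
    stop("unknown correlation_method: ", cfg$correlation_method)
  }
  if (!cfg$jaccard_mode %in% c("quantitative", "binary")) {
    stop("unknown jaccard_mode: ", cfg$jaccard_mode)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file of flat key-value pairs.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A [pipeline_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
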