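# Import, validation and summaries of OTU relative-abundance tables.
#
# Abundances are percentages of classified reads; rows need not sum to 100
# (unclassified reads are simply absent), but may not exceed it.

GENOTYPE_LEVELS  <- c("DKO", "nonDKO")
TREATMENT_LEVELS <- c("splenda", "metronidazole", "vancomycin", "streptomycin",
                      "none")
SEX_LEVELS       <- c("M", "F", "unknown")

#' Construct a validated OTU relative-abundance table
#'
#' @param values Numeric matrix, one row per sample, one column per OTU,
#'   entries in percent of classified reads.
#' @param metadata Data frame with one row per sample and columns
#'   `sample_id`, `genotype` (`"DKO"`/`"nonDKO"`), `treatment`
#'   (`"splenda"`, `"metronidazole"`, `"vancomycin"`, `"streptomycin"`,
#'   `"none"`) and optionally `sex` (`"M"`/`"F"`/`"unknown"`). Rows are
#'   matched to `rownames(values)` by `sample_id`.
#' @param total_tolerance Allowed overshoot of a row total above 100 percent
#'   (guards against rounding in upstream percent calculations).
#' @return An object of class `abundance_table`: a list with elements
#'   `values` (the matrix) and `samples` (the aligned metadata).
#' @export
abundance_table <- function(values, metadata, total_tolerance = 0.5) {
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop("no samples")
  if (is.null(colnames(values)) || anyNA(colnames(values)) ||
      any(colnames(values) == "")) {
    stop("OTU columns must be named")
  }
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup)) {
    stop("duplicate OTU names: ", paste(dup, collapse = ", "))
  }
  if (!is.numeric(values) || anyNA(values)) {
    stop("abundance values must be numeric and non-missing")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance for sample '%s', OTU '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  totals <- rowSums(values)
  if (any(totals > 100 + total_tolerance)) {
    bad <- which.max(totals)
    stop(sprintf("row total %.2f%% exceeds 100%% for sample '%s'",
                 totals[bad], rownames(values)[bad]))
  }

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  req <- c("sample_id", "genotype", "treatment")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"sex" %in% names(metadata)) metadata$sex <- "unknown"
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  }
  if (is.null(rownames(values))) {
    if (nrow(values) != nrow(metadata)) {
      stop("unnamed sample rows cannot be matched to metadata of ",
           "different length")
    }
    rownames(values) <- metadata$sample_id
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids in abundance rows")
  }

  unmatched_samples <- setdiff(rownames(values), metadata$sample_id)
  if (length(unmatched_samples)) {
    stop("sample(s) without metadata: ",
         paste(unmatched_samples, collapse = ", "))
  }
  unmatched_meta <- setdiff(metadata$sample_id, rownames(values))
  if (length(unmatched_meta)) {
    warning("metadata row(s) without abundance data dropped: ",
            paste(unmatched_meta, collapse = ", "))
    metadata <- metadata[metadata$sample_id %in% rownames(values), ,
                         drop = FALSE]
  }
  metadata <- metadata[match(rownames(values), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL

  bad_gt <- setdiff(unique(metadata$genotype), GENOTYPE_LEVELS)
  if (length(bad_gt)) stop("unknown genotype: ", paste(bad_gt, collapse = ", "))
  bad_tr <- setdiff(unique(metadata$treatment), TREATMENT_LEVELS)
  if (length(bad_tr)) {
    stop("unknown treatment: ", paste(bad_tr, collapse = ", "))
  }
  bad_sex <- setdiff(unique(metadata$sex), SEX_LEVELS)
  if (length(bad_sex)) stop("unknown sex: ", paste(bad_sex, collapse = ", "))
  nondko_bad <- metadata$genotype == "nonDKO" &
    !metadata$treatment %in% c("splenda", "none")
  if (any(nondko_bad)) {
    stop("non-DKO samples may only carry treatment 'splenda' or 'none': ",
         paste(metadata$sample_id[nondko_bad], collapse = ", "))
  }

  structure(list(values = values, samples = metadata),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d OTUs\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(genotype = x$samples$genotype, treatment = x$samples$treatment)
  print(tab)
  cat(sprintf("row totals (classified %%): %.2f - %.2f\n",
              min(rowSums(x$values)), max(rowSums(x$values))))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' OTU identifiers of an abundance table
#' @param table An [abundance_table()].
#' @return Character vector of OTU names, in column order.
#' @export
otu_ids <- function(table) colnames(table$values)

#' Sample identifiers of an abundance table
#' @param table An [abundance_table()].
#' @return Character vector of sample ids, in row order.
#' @export
sample_ids <- function(table) table$samples$sample_id

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an OTU relative-abundance table with sample metadata
#'
#' The abundance file is delimited text (TSV or CSV by extension) with a
#' header row of OTU names, a first column of sample identifiers and one row
#' per sample, values in percent. The metadata file is a CSV keyed by
#' `sample_id` with `genotype`, `treatment` and optionally `sex` columns.
#'
#' @param path Path to the abundance table.
#' @param metadata_path Path to the sample metadata CSV.
#' @param ... Passed to [abundance_table()] (e.g. `total_tolerance`).
#' @return A validated [abundance_table()], rows aligned to metadata;
#'   metadata rows with no abundance data are reported via warning.
#' @export
read_abundance_table <- function(path, metadata_path, ...) {
  raw <- utils::read.delim(path, sep = .delim_for(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no samples")
  ids <- as.character(raw[[1L]])
  values <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  metadata <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  abundance_table(values, metadata, ...)
}

#' Write an abundance table and its metadata
#'
#' @param table An [abundance_table()].
#' @param path Output path for the abundance matrix (TSV or CSV by
#'   extension).
#' @param metadata_path Optional output path for the metadata CSV.
#' @return Invisibly, `table`.
#' @export
write_abundance_table <- function(table, path, metadata_path = NULL) {
  df <- data.frame(sample_id = rownames(table$values),
                   table$values, check.names = FALSE)
  utils::write.table(df, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.csv(table$samples, metadata_path, row.names = FALSE)
  }
  invisible(table)
}

#' Read a mothur `.shared` count table as relative abundances
#'
#' Counts per OTU are converted to percent of the per-sample row total
#' (all classified reads), so row totals are exactly 100.
#'
#' @param path Path to a mothur `.shared` file (columns `label`, `Group`,
#'   `numOtus`, then one count column per OTU).
#' @param metadata Metadata data frame as for [abundance_table()].
#' @return An [abundance_table()] in percent units.
#' @export
read_mothur_shared <- function(path, metadata) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  req <- c("label", "Group", "numOtus")
  if (!all(req %in% names(raw))) {
    stop("not a mothur .shared file: needs columns ",
         paste(req, collapse = ", "))
  }
  counts <- as.matrix(raw[, setdiff(names(raw), req), drop = FALSE])
  storage.mode(counts) <- "double"
  rownames(counts) <- as.character(raw$Group)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(rownames(counts)[totals == 0], collapse = ", "))
  }
  abundance_table(sweep(counts, 1L, totals, "/") * 100, metadata)
}

#' Subset an abundance table
#'
#' @param table An [abundance_table()].
#' @param samples Character vector of sample ids to keep (default all).
#' @param otus Character vector of OTU ids to keep (default all).
#' @return The subsetted [abundance_table()].
#' @export
subset_table <- function(table, samples = sample_ids(table),
                         otus = otu_ids(table)) {
  stopifnot(all(samples %in% sample_ids(table)),
            all(otus %in% otu_ids(table)))
  keep <- match(samples, rownames(table$values))
  abundance_table(table$values[keep, otus, drop = FALSE],
                  table$samples[keep, , drop = FALSE])
}

#' Filter OTUs by a minimum-abundance detection rule
#'
#' Retains exactly the OTUs whose abundance exceeds `min_percent` (strictly)
#' in at least `min_samples` samples; the sample set is unchanged. The
#' default reproduces the study's inclusion rule: abundance greater than
#' 0.5% in at least one sample.
#'
#' @param table An [abundance_table()].
#' @param min_percent Detection threshold in percent (strict inequality).
#' @param min_samples Minimum number of samples above threshold.
#' @return The filtered [abundance_table()] (possibly with zero OTUs).
#' @export
#' @examples
#' study <- make_study(simulation_config(seed = 1))
#' filtered <- filter_otus(study$table)
#' ncol(filtered$values)
filter_otus <- function(table, min_percent = 0.5, min_samples = 1L) {
  keep <- colSums(table$values > min_percent) >= min_samples
  out <- table
  out$values <- table$values[, keep, drop = FALSE]
  out
}

#' Construct a group profile (mean abundance per OTU)
#'
#' @param group_label Character scalar naming the group.
#' @param mean_abundance Named non-negative numeric vector of mean
#'   abundances in percent, one entry per OTU.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(group_label, mean_abundance) {
  stopifnot(is.character(group_label), length(group_label) == 1L)
  if (is.null(names(mean_abundance)) || anyNA(names(mean_abundance))) {
    stop("mean_abundance must be a named vector of OTU means")
  }
  if (any(mean_abundance < 0)) stop("group profile values must be >= 0")
  structure(list(group_label = group_label,
                 mean_abundance = mean_abundance),
            class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat(sprintf("group_profile '%s': %d OTUs, total %.2f%%\n",
              x$group_label, length(x$mean_abundance),
              sum(x$mean_abundance)))
  invisible(x)
}

#' Per-group arithmetic mean abundance profiles
#'
#' @param table An [abundance_table()].
#' @param group_by Character vector of metadata column names to group by
#'   (e.g. `"treatment"` or `c("genotype", "treatment")`). Every sample must
#'   fall in exactly one group; missing grouping values are an error.
#' @return Named list of [group_profile()] objects.
#' @export
group_means <- function(table, group_by = "treatment") {
  miss <- setdiff(group_by, names(table$samples))
  if (length(miss)) {
    stop("unknown metadata field(s): ", paste(miss, collapse = ", "))
  }
  keys <- table$samples[, group_by, drop = FALSE]
  if (anyNA(keys)) stop("sample(s) with missing group assignment")
  label <- do.call(paste, c(as.list(keys), sep = "."))
  out <- lapply(split(seq_len(nrow(table$values)), label), function(idx) {
    means <- colMeans(table$values[idx, , drop = FALSE])
    group_profile(label[idx[1L]], means)
  })
  out[order(names(out))]
}

#' Total classified abundance of a group profile
#'
#' @param profile A [group_profile()].
#' @return Sum of the per-OTU mean abundances, in percent.
#' @export
total_classified <- function(profile) {
  stopifnot(inherits(profile, "group_profile"))
  if (length(profile$mean_abundance) == 0L) stop("empty profile")
  sum(profile$mean_abundance)
}

#' Core microbiota shared between diseased and control groups
#'
#' An OTU belongs to the core when its mean abundances in the two groups
#' differ by less than `fold_max` (strictly), its differential-abundance
#' p-value exceeds `p_min` (strictly), and its mean is at least `min_mean`
#' in *both* groups. The mean floor keeps trace OTUs sitting at the
#' reporting floor (whose fold ratio is uninformative) out of the core.
#'
#' @param dko,nondko [group_profile()] objects over the same OTU set.
#' @param per_otu_p Optional named vector of p-values (e.g. from
#'   [differential_otus()]); OTUs missing from it are treated as
#'   non-significant (p = 1).
#' @param fold_max Strict upper bound on the mean-abundance fold ratio.
#' @param p_min Strict lower bound on the p-value.
#' @param min_mean Minimum mean abundance (percent) required in both groups.
#' @return Character vector of core OTU ids, in the profiles' order.
#' @export
#' @examples
#' core_microbiota(reference_profile("splenda"), reference_profile("nondko"))
core_microbiota <- function(dko, nondko, per_otu_p = NULL, fold_max = 2,
                            p_min = 0.09, min_mean = 0.2) {
  stopifnot(inherits(dko, "group_profile"), inherits(nondko, "group_profile"))
  a <- dko$mean_abundance
  b <- nondko$mean_abundance
  if (!setequal(names(a), names(b))) {
    only <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
    stop("OTU(s) present in only one profile: ", paste(only, collapse = ", "))
  }
  b <- b[names(a)]
  p <- setNames(rep(1, length(a)), names(a))
  if (!is.null(per_otu_p)) {
    known <- intersect(names(per_otu_p), names(p))
    p[known] <- per_otu_p[known]
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  fold <- ifelse(hi == 0, 1, ifelse(lo == 0, Inf, hi / lo))
  names(a)[fold < fold_max & p > p_min & lo >= min_mean]
}
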