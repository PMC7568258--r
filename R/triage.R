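# Three-way candidate triage: cured-vs-sick extreme screen, sign-harmonized
# abundance-pathology correlation panel, DKO-vs-non-DKO shifts, and the
# consensus verdict per OTU (provocative vs beneficial/opportunistic).

#' Stratify mice into cured and sick extremes by overall score
#'
#' Cured: overall score at most `cured_max` (default 1, matching the
#' published 0.5-1 cured band). Sick: score at least `sick_min` (default
#' 5). Only DKO mice are eligible; pass DKO scores only, or supply
#' `genotype` to filter.
#'
#' @param scores Named numeric vector of overall scores (names are sample
#'   ids).
#' @param cured_max,sick_min Score thresholds.
#' @param genotype Optional character vector aligned with `scores`;
#'   non-`"DKO"` entries are excluded before stratification.
#' @return List of class `extreme_groups` with `cured_ids` and `sick_ids`
#'   (disjoint by construction since `cured_max < sick_min`).
#' @export
stratify_extremes <- function(scores, cured_max = 1, sick_min = 5,
                              genotype = NULL) {
  stopifnot(cured_max < sick_min)
  if (is.null(names(scores))) stop("scores must be named by sample id")
  if (!is.null(genotype)) {
    stopifnot(length(genotype) == length(scores))
    scores <- scores[genotype == "DKO"]
  }
  cured <- names(scores)[scores <= cured_max]
  sick <- names(scores)[scores >= sick_min]
  if (length(cured) == 0L || length(sick) == 0L) {
    warning(sprintf("extreme group(s) empty: %d cured, %d sick",
                    length(cured), length(sick)))
  }
  structure(list(cured_ids = cured, sick_ids = sick),
            class = "extreme_groups")
}

.pooled_t_p <- function(a, b) {
  # pairwise two-sample pooled t; degenerate inputs give p = 1
  if (var(a) == 0 && var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  tryCatch(stats::t.test(a, b, var.equal = TRUE)$p.value,
           error = function(e) 1)
}

#' Cured-versus-sick abundance screen
#'
#' For each OTU, the ratio of floored mean abundance in cured over sick
#' mice (ratio < 1: candidate provocative -- the OTU is depleted where
#' disease is absent; ratio > 1: candidate beneficial or opportunistic), a
#' pairwise two-sample t-test, and a family-wise adjusted p-value. The
#' adjustment family defaults to the OTUs passing the pairwise test at
#' `family_alpha` (the named candidates); OTUs outside the family get
#' `NA` adjusted values.
#'
#' @param table An [abundance_table()].
#' @param groups An `extreme_groups` object from [stratify_extremes()].
#' @param floor Detection floor in percent (shared with
#'   [differential_otus()]).
#' @param adjust_method `"bonferroni"` (default), `"holm"` or `"BH"`.
#' @param family `"candidates"` (adjust over OTUs with pairwise p <=
#'   `family_alpha`) or `"all"` (adjust over every OTU).
#' @param family_alpha Pairwise-test threshold defining the candidate
#'   family.
#' @return Data frame per OTU: `otu_id`, `ratio_cured_over_sick`,
#'   `pairwise_p`, `adjusted_p`, `direction` (`"provocative"`,
#'   `"beneficial_or_opportunistic"` or `"none"` at ratio exactly 1).
#' @export
cured_sick_screen <- function(table, groups, floor = 0.1,
                              adjust_method = c("bonferroni", "holm", "BH"),
                              family = c("candidates", "all"),
                              family_alpha = 0.05) {
  adjust_method <- match.arg(adjust_method)
  family <- match.arg(family)
  stopifnot(inherits(groups, "extreme_groups"))
  if (length(groups$cured_ids) == 0L || length(groups$sick_ids) == 0L) {
    stop("both extreme groups must be non-empty")
  }
  v <- table$values
  ic <- match(groups$cured_ids, rownames(v))
  is <- match(groups$sick_ids, rownames(v))
  if (anyNA(ic) || anyNA(is)) stop("extreme group sample(s) not in table")
  ratio <- vapply(seq_len(ncol(v)), function(j) {
    floored_mean_ratio(v[ic, j], v[is, j], floor)
  }, numeric(1))
  p <- vapply(seq_len(ncol(v)), function(j) {
    .pooled_t_p(v[ic, j], v[is, j])
  }, numeric(1))
  adjusted <- rep(NA_real_, length(p))
  in_family <- if (family == "all") rep(TRUE, length(p)) else p <= family_alpha
  adjusted[in_family] <- stats::p.adjust(p[in_family], method = adjust_method)
  data.frame(
    otu_id = otu_ids(table),
    ratio_cured_over_sick = ratio,
    pairwise_p = p,
    adjusted_p = adjusted,
    direction = ifelse(ratio < 1, "provocative",
                ifelse(ratio > 1, "beneficial_or_opportunistic", "none")),
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation with degenerate-input handling
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List of class `correlation_result`: `r`, `r_squared`, `n`,
#'   `slope`, `intercept` (least-squares line of `y` on `x`) and
#'   `degenerate` (`TRUE` when either input has zero variance, in which
#'   case `r = 0`).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (var(x) == 0 || var(y) == 0) {
    res <- list(r = 0, r_squared = 0, n = length(x),
                slope = NA_real_, intercept = NA_real_, degenerate = TRUE)
  } else {
    r <- stats::cor(x, y, method = method)
    slope <- stats::cov(x, y) / var(x)
    res <- list(r = r, r_squared = r^2, n = length(x),
                slope = slope, intercept = mean(y) - slope * mean(x),
                degenerate = FALSE)
  }
  structure(res, class = "correlation_result")
}

#' Per-OTU, per-marker correlation panel
#'
#' Pearson (by default) correlation of each OTU's abundance with each of
#' the five pathology markers across mice, typically all DKO mice from the
#' control and antibiotic sets. Degenerate correlations (zero variance)
#' are reported as 0 and flagged.
#'
#' @param table An [abundance_table()] (samples must match the panel).
#' @param panels A `marker_panel` (see [marker_panel()]) with `sample_id`
#'   column or rows aligned to the table.
#' @param method Correlation type.
#' @return Data frame: `otu_id`, one `r_<marker>` column per marker, an
#'   `n_degenerate` count, plus `harmonized_mean_r` (see
#'   [harmonized_average()]).
#' @export
marker_correlation_panel <- function(table, panels,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  markers <- names(marker_directions())
  v <- table$values
  if ("sample_id" %in% names(panels)) {
    idx <- match(rownames(v), panels$sample_id)
    if (anyNA(idx)) {
      stop("marker panel missing sample(s): ",
           paste(rownames(v)[is.na(idx)], collapse = ", "))
    }
    panels <- panels[idx, , drop = FALSE]
  } else if (nrow(panels) != nrow(v)) {
    stop("marker panel and table have different numbers of mice")
  }
  rmat <- matrix(NA_real_, ncol(v), length(markers),
                 dimnames = list(otu_ids(table), markers))
  degen <- integer(ncol(v))
  for (j in seq_len(ncol(v))) {
    for (m in markers) {
      cr <- correlate(v[, j], panels[[m]], method = method)
      rmat[j, m] <- cr$r
      degen[j] <- degen[j] + cr$degenerate
    }
  }
  out <- data.frame(otu_id = otu_ids(table), rmat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out)[-1L] <- paste0("r_", markers)
  out$n_degenerate <- degen
  out$harmonized_mean_r <- apply(rmat, 1L, harmonized_average)
  rownames(out) <- NULL
  out
}

#' Sign-harmonized average of the five marker correlations
#'
#' Coefficients for markers where a higher value means better health (the
#' Paneth cell fraction) are sign-flipped so that every coefficient points
#' in the "more pathology" direction, then the five are averaged. A
#' positive result means higher abundance goes with more pathology.
#'
#' @param per_marker_r Numeric vector of five correlation coefficients,
#'   named by marker (or in [marker_directions()] order).
#' @param directions Named logical vector of `higher_is_worse` flags.
#' @return The harmonized mean coefficient.
#' @export
harmonized_average <- function(per_marker_r, directions = marker_directions()) {
  stopifnot(length(per_marker_r) == length(directions))
  if (!is.null(names(per_marker_r))) {
    if (!setequal(names(per_marker_r), names(directions))) {
      stop("marker names do not match direction flags")
    }
    per_marker_r <- per_marker_r[names(directions)]
  }
  mean(ifelse(directions, 1, -1) * per_marker_r)
}

#' Correlation of combined OTU abundances with a marker
#'
#' Sums the listed OTUs' abundances per mouse, then correlates the sum with
#' the marker values; used to ask whether several taxa jointly track
#' pathology better than any one of them.
#'
#' @param table An [abundance_table()].
#' @param otus Character vector of OTU ids to combine.
#' @param marker_values Numeric vector of marker values aligned to the
#'   table's samples.
#' @param method Correlation type.
#' @return A `correlation_result` (see [correlate()]).
#' @export
combined_correlation <- function(table, otus, marker_values,
                                 method = c("pearson", "spearman")) {
  miss <- setdiff(otus, otu_ids(table))
  if (length(miss)) stop("unknown OTU(s): ", paste(miss, collapse = ", "))
  combined <- rowSums(table$values[, otus, drop = FALSE])
  correlate(combined, marker_values, method = method)
}

#' Dilution adjustment of a target OTU's abundance
#'
#' Renormalizes the target abundance to the composition excluding a
#' blooming "diluter" OTU: `target / (100 - diluter) * 100`. Used to ask
#' whether an apparent drop in the target merely reflects crowding-out by
#' the diluter within the fixed 100-percent composition.
#'
#' @param target Target OTU abundance(s) in percent.
#' @param diluter Diluter OTU abundance(s) in percent, strictly below 100.
#' @return Adjusted target abundance(s) in percent.
#' @export
#' @examples
#' dilution_adjust(40, 20)  # 50
dilution_adjust <- function(target, diluter) {
  stopifnot(all(target >= 0), all(diluter >= 0))
  if (any(diluter >= 100)) stop("diluter abundance must be below 100 percent")
  target / (100 - diluter) * 100
}

#' Consensus classification of candidate OTUs
#'
#' Combines three signals per OTU: (i) expansion (pathology-positive) or
#' contraction (negative) in DKO versus non-DKO mice, counted only when
#' the shift is significant (|fold| >= `fc_min` at q <= `fdr_max`);
#' (ii) the cured/sick direction (ratio < 1 positive, > 1 negative), when
#' available; (iii) the harmonized correlation when |r| >= `r_threshold`
#' (its sign giving the direction). The verdict is `"provocative"` with at
#' least two concordant pathology-positive signals,
#' `"beneficial_or_opportunistic"` with at least two concordant negatives,
#' otherwise `"indeterminate"`.
#'
#' @param records Data frame with columns `otu_id`,
#'   `ratio_cured_over_sick` (may be `NA`), `harmonized_mean_r`.
#' @param dko_vs_nondko Output of [differential_otus()] for DKO versus
#'   non-DKO (fold change DKO over non-DKO), or `NULL` to drop that signal.
#' @param r_threshold Moderate-correlation threshold (default 0.3).
#' @param fc_min,fdr_max Shift-signal call criteria.
#' @return `records` with added columns `signal_shift`, `signal_ratio`,
#'   `signal_correlation` (each -1, 0 or +1) and `verdict`.
#' @export
consensus_classify <- function(records, dko_vs_nondko = NULL,
                               r_threshold = 0.3, fc_min = 1.2,
                               fdr_max = 0.05) {
  n <- nrow(records)
  shift <- integer(n)
  if (!is.null(dko_vs_nondko)) {
    idx <- match(records$otu_id, dko_vs_nondko$otu_id)
    sig <- !is.na(idx) & dko_vs_nondko$significant[idx]
    lfc <- dko_vs_nondko$log2_fold_change[idx]
    shift <- ifelse(sig & lfc > 0, 1L, ifelse(sig & lfc < 0, -1L, 0L))
  }
  ratio <- records$ratio_cured_over_sick
  sig_ratio <- ifelse(is.na(ratio), 0L,
               ifelse(ratio < 1, 1L, ifelse(ratio > 1, -1L, 0L)))
  r <- records$harmonized_mean_r
  sig_cor <- ifelse(!is.na(r) & abs(r) >= r_threshold, sign(r), 0L)
  pos <- (shift > 0) + (sig_ratio > 0) + (sig_cor > 0)
  neg <- (shift < 0) + (sig_ratio < 0) + (sig_cor < 0)
  records$signal_shift <- shift
  records$signal_ratio <- sig_ratio
  records$signal_correlation <- as.integer(sig_cor)
  records$verdict <- ifelse(pos >= 2, "provocative",
                     ifelse(neg >= 2, "beneficial_or_opportunistic",
                            "indeterminate"))
  records
}

#' Full candidate triage of an abundance table
#'
#' Orchestrates the three analyses: stratifies DKO mice into cured/sick
#' extremes from the marker panel's overall scores and screens abundances
#' between them; computes the sign-harmonized correlation panel across all
#' DKO mice; screens DKO (Splenda control) versus non-DKO abundances; and
#' issues consensus verdicts.
#'
#' @param table An [abundance_table()] covering DKO and non-DKO mice.
#' @param panels A `marker_panel` for the DKO mice (with `sample_id`).
#' @param config A [pipeline_config()] carrying the thresholds.
#' @return List of class `triage_result`: `records` (per-OTU triage table
#'   with verdicts), `screen` (cured/sick screen), `correlations` (the
#'   panel), `dko_vs_nondko` (differential screen), `groups` (the extreme
#'   groups).
#' @export
#' @examples
#' study <- make_study(simulation_config(seed = 1))
#' tri <- triage_otus(study$table, study$panels)
#' table(tri$records$verdict)
triage_otus <- function(table, panels, config = pipeline_config()) {
  dko <- table$samples$genotype == "DKO"
  dko_ids <- sample_ids(table)[dko]
  dko_table <- subset_table(table, samples = dko_ids)
  if ("sample_id" %in% names(panels)) {
    panels_dko <- panels[panels$sample_id %in% dko_ids, , drop = FALSE]
  } else {
    stop("marker panel needs a sample_id column for triage")
  }
  scores <- setNames(panels_dko$overall_score, panels_dko$sample_id)

  groups <- suppressWarnings(
    stratify_extremes(scores, config$cured_max, config$sick_min))
  screen <- NULL
  if (length(groups$cured_ids) > 0L && length(groups$sick_ids) > 0L) {
    screen <- cured_sick_screen(dko_table, groups, floor = config$floor,
                                adjust_method = config$adjust_method,
                                family = config$adjust_family,
                                family_alpha = config$family_alpha)
  }
  correlations <- marker_correlation_panel(dko_table, panels_dko,
                                           method = config$correlation_method)

  shift <- NULL
  if (any(!dko)) {
    shift_meta <- table$samples
    shift_grp <- ifelse(shift_meta$genotype == "DKO" &
                          shift_meta$treatment %in% c("splenda", "none"),
                        "dko_control",
                 ifelse(shift_meta$genotype == "nonDKO", "nondko", NA))
    keep <- !is.na(shift_grp)
    sub <- subset_table(table, samples = sample_ids(table)[keep])
    sub$samples$shift_group <- shift_grp[keep]
    shift <- differential_otus(sub, "shift_group",
                               c("dko_control", "nondko"),
                               fc_min = config$fc_min,
                               fdr_max = config$fdr_max,
                               floor = config$floor)
  }

  records <- data.frame(otu_id = otu_ids(dko_table),
                        stringsAsFactors = FALSE)
  if (!is.null(screen)) {
    records$ratio_cured_over_sick <- screen$ratio_cured_over_sick
    records$pairwise_p <- screen$pairwise_p
    records$adjusted_p <- screen$adjusted_p
  } else {
    records$ratio_cured_over_sick <- NA_real_
    records$pairwise_p <- NA_real_
    records$adjusted_p <- NA_real_
  }
  records$harmonized_mean_r <- correlations$harmonized_mean_r
  if (!is.null(shift)) {
    idx <- match(records$otu_id, shift$otu_id)
    records$dko_log2fc <- shift$log2_fold_change[idx]
    records$dko_q <- shift$q_value[idx]
  }
  records <- consensus_classify(records, shift,
                                r_threshold = config$r_threshold,
                                fc_min = config$fc_min,
                                fdr_max = config$fdr_max)
  structure(list(records = records, screen = screen,
                 correlations = correlations, dko_vs_nondko = shift,
                 groups = groups),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("triage_result: %d OTUs; %d cured / %d sick mice\n",
              nrow(x$records), length(x$groups$cured_ids),
              length(x$groups$sick_ids)))
  print(table(verdict = x$records$verdict))
  invisible(x)
}
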