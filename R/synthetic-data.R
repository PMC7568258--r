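# Synthetic study generator: Dirichlet per-mouse compositions around the
# built-in group profiles, plus pathology markers linked to the designated
# provocative OTUs through a latent severity variable. The generator
# emulates the study layout: 4 DKO treatment groups of 8 mice, 6 non-DKO
# mice, 24 OTUs, classified row totals below 100 percent.

#' Configuration of the synthetic-study generator
#'
#' Defaults emulate the published study conditions: the five built-in
#' group-mean profiles ([reference_profiles()]), 8 DKO mice per treatment
#' group plus 6 non-DKO mice, Dirichlet concentration 50 (realistic
#' mouse-to-mouse scatter), provocative OTUs Lactobacillus and
#' Clostridiaceae-1 driving a latent severity `l = beta0 + beta1 * A +
#' N(0, sigma)` (A: summed provocative abundance in percent), and row
#' totals drawn uniformly from the classified-fraction range 75-98
#' percent. `beta0 = 1.2`, `beta1 = 0.07`, `sigma = 0.8` place the
#' simulated cured and sick extremes near the published group means
#' (about 0.8 and 5.9).
#'
#' @param group_profiles Named list of [group_profile()] objects.
#' @param n_per_group Named integer vector of mice per group (all >= 2).
#' @param concentration Dirichlet concentration scalar (> 0); larger
#'   values give less mouse-to-mouse scatter.
#' @param provocative_otus OTUs whose summed abundance drives severity.
#' @param beta0,beta1 Severity link intercept and slope (score units;
#'   slope per percent abundance).
#' @param sigma Severity noise standard deviation (>= 0).
#' @param marker_sigma Noise scale of the downstream markers (fraction
#'   units; >= 0).
#' @param total_range Length-2 range of per-mouse classified row totals
#'   (percent).
#' @param nondko_groups Group labels generated as non-DKO genotype.
#' @param seed Optional integer seed; when set, [sample_compositions()]
#'   and [make_study()] reset the RNG for bit-identical re-runs.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(group_profiles = NULL,
                              n_per_group = reference_group_sizes(),
                              concentration = 50,
                              provocative_otus = c("Lactobacillus",
                                                   "Clostridiaceae-1"),
                              beta0 = 1.2, beta1 = 0.07, sigma = 0.8,
                              marker_sigma = 0.03,
                              total_range = c(75, 98),
                              nondko_groups = "nondko",
                              seed = NULL) {
  if (is.null(group_profiles)) {
    group_profiles <- lapply(
      c("splenda", "nondko", "metronidazole", "vancomycin", "streptomycin"),
      reference_profile)
    names(group_profiles) <- vapply(group_profiles, `[[`, character(1),
                                    "group_label")
  }
  stopifnot(all(vapply(group_profiles, inherits, logical(1),
                       "group_profile")))
  if (!setequal(names(n_per_group), names(group_profiles))) {
    stop("n_per_group and group_profiles must name the same groups")
  }
  if (any(n_per_group < 2L)) stop("every group needs at least 2 mice")
  stopifnot(concentration > 0, sigma >= 0, marker_sigma >= 0,
            length(total_range) == 2L, total_range[1L] <= total_range[2L],
            total_range[1L] > 0, total_range[2L] <= 100)
  otus <- names(group_profiles[[1L]]$mean_abundance)
  for (gp in group_profiles) {
    if (!identical(names(gp$mean_abundance), otus)) {
      stop("all group profiles must cover the same OTUs in the same order")
    }
  }
  miss <- setdiff(provocative_otus, otus)
  if (length(miss)) {
    stop("provocative OTU(s) not in profiles: ", paste(miss, collapse = ", "))
  }
  structure(list(group_profiles = group_profiles,
                 n_per_group = n_per_group,
                 concentration = concentration,
                 provocative_otus = provocative_otus,
                 beta0 = beta0, beta1 = beta1, sigma = sigma,
                 marker_sigma = marker_sigma,
                 total_range = total_range,
                 nondko_groups = nondko_groups,
                 seed = seed),
            class = "simulation_config")
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s == 0) { g[which.max(alpha)] <- 1; s <- 1 }  # pathological tiny alpha
  g / s
}

#' Draw per-mouse compositions from the configured Dirichlet model
#'
#' Each mouse's composition is Dirichlet with mean equal to its group's
#' normalized profile and the configured concentration, scaled to a row
#' total drawn uniformly from `total_range` (emulating the unclassified
#' read fraction). Metadata records group, genotype (non-DKO for groups in
#' `nondko_groups`), treatment and alternating sex.
#'
#' @param config A [simulation_config()]. If `config$seed` is set the RNG
#'   is reset first, so repeated calls are bit-identical.
#' @return An [abundance_table()] with a `group` metadata column.
#' @export
sample_compositions <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  groups <- names(config$group_profiles)
  rows <- list(); meta <- list()
  for (g in groups) {
    prof <- config$group_profiles[[g]]$mean_abundance
    share <- prof / sum(prof)
    alpha <- config$concentration * share
    n <- config$n_per_group[[g]]
    for (i in seq_len(n)) {
      comp <- .rdirichlet(alpha)
      total <- stats::runif(1L, config$total_range[1L],
                            config$total_range[2L])
      id <- sprintf("%s_%02d", g, i)
      rows[[id]] <- comp * total
      meta[[id]] <- data.frame(
        sample_id = id,
        genotype = if (g %in% config$nondko_groups) "nonDKO" else "DKO",
        treatment = if (g %in% config$nondko_groups) "splenda"
                    else if (g %in% TREATMENT_LEVELS) g else "none",
        sex = if (i %% 2L == 1L) "M" else "F",
        group = g,
        stringsAsFactors = FALSE
      )
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- names(config$group_profiles[[1L]]$mean_abundance)
  abundance_table(values, do.call(rbind, meta))
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate linked pathology markers for simulated mice
#'
#' Latent severity `l = beta0 + beta1 * A + N(0, sigma)` with `A` the
#' summed abundance of the designated provocative OTUs. The overall score
#' is `l` clipped to \[0, 10\] and rounded to the nearest 0.5; crypt
#' exfoliation, crypt abscesses and apoptosis are increasing saturating
#' (logistic) functions of `l` plus noise; the Paneth cell fraction is a
#' decreasing function of `l` plus noise, clipped to \[0, 1\]. The link
#' shapes are a modelling choice -- only monotone co-variation with
#' severity is relied on downstream.
#'
#' @param table An [abundance_table()] from [sample_compositions()].
#' @param config A [simulation_config()].
#' @return A `marker_panel` with `sample_id` and a `latent_severity`
#'   attribute recording `l` per mouse.
#' @export
generate_markers <- function(table, config) {
  stopifnot(inherits(config, "simulation_config"))
  A <- rowSums(table$values[, config$provocative_otus, drop = FALSE])
  n <- nrow(table$values)
  l <- config$beta0 + config$beta1 * A + stats::rnorm(n, 0, config$sigma)
  ms <- config$marker_sigma
  score <- round(pmin(pmax(l, 0), 10) * 2) / 2
  exfoliation <- .clip01(0.45 * stats::plogis((l - 4) / 1.5) +
                           stats::rnorm(n, 0, ms))
  abscesses <- pmax(0, 2.5 * stats::plogis((l - 4) / 1.5) +
                      stats::rnorm(n, 0, 5 * ms))
  apoptosis <- pmax(0, 0.45 * stats::plogis((l - 3) / 1.5) +
                      stats::rnorm(n, 0, ms))
  paneth <- .clip01(1 - 0.95 * stats::plogis((l - 3) / 1.2) +
                      stats::rnorm(n, 0, ms))
  panel <- data.frame(
    sample_id = sample_ids(table),
    overall_score = score,
    exfoliation_fraction = exfoliation,
    paneth_fraction = paneth,
    abscesses_per_field = abscesses,
    apoptosis_per_crypt = apoptosis,
    stringsAsFactors = FALSE
  )
  attr(panel, "directions") <- marker_directions()
  attr(panel, "latent_severity") <- setNames(l, sample_ids(table))
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Generate a complete synthetic study
#'
#' Composes [sample_compositions()] and [generate_markers()] under one
#' seed and optionally writes the study in the pipeline's external
#' formats: abundance TSV, metadata CSV, marker CSV and a JSON truth
#' record of the generative parameters.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory (created if needed).
#' @return List of class `synthetic_study`: `table`, `panels`, `truth`.
#' @export
#' @examples
#' study <- make_study(simulation_config(seed = 42))
#' dim(study$table$values)  # 38 mice x 24 OTUs under defaults
make_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  inner <- config
  inner$seed <- NULL  # one reset for the whole study, streams chained
  table <- sample_compositions(inner)
  panels <- generate_markers(table, inner)
  truth <- list(beta0 = config$beta0, beta1 = config$beta1,
                sigma = config$sigma, marker_sigma = config$marker_sigma,
                concentration = config$concentration,
                provocative_otus = config$provocative_otus,
                total_range = config$total_range,
                n_per_group = as.list(config$n_per_group),
                seed = config$seed)
  study <- structure(list(table = table, panels = panels, truth = truth),
                     class = "synthetic_study")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_abundance_table(table, file.path(dir, "abundance.tsv"),
                          file.path(dir, "metadata.csv"))
    utils::write.csv(as.data.frame(panels),
                     file.path(dir, "markers.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  study
}

#' Calibrate the severity slope for a target combined R-squared
#'
#' Computes analytically, from the generative parameters, the slope
#' `beta1` for which the latent severity explains a given fraction of its
#' variance through the combined provocative-OTU abundance `A` across the
#' DKO mice: `R^2 = beta1^2 Var(A) / (beta1^2 Var(A) + sigma^2)`, so
#' `beta1 = sigma * sqrt(R^2 / (1 - R^2)) / sd(A)`. `Var(A)` follows from
#' the Dirichlet aggregation property (the provocative share is Beta
#' distributed within each group), the independent uniform row total, and
#' the mixture over DKO groups weighted by group size.
#'
#' @param config A [simulation_config()].
#' @param r_squared Target fraction of latent severity variance explained
#'   (in (0, 1)).
#' @return The calibrated slope `beta1` (score units per percent).
#' @export
calibrate_score_slope <- function(config, r_squared = 0.5) {
  stopifnot(inherits(config, "simulation_config"),
            r_squared > 0, r_squared < 1, config$sigma > 0)
  t1 <- config$total_range[1L]; t2 <- config$total_range[2L]
  ET <- (t1 + t2) / 2
  ET2 <- (t1^2 + t1 * t2 + t2^2) / 3
  c0 <- config$concentration
  dko <- setdiff(names(config$group_profiles), config$nondko_groups)
  w <- config$n_per_group[dko] / sum(config$n_per_group[dko])
  EA <- 0; EA2 <- 0
  for (g in dko) {
    prof <- config$group_profiles[[g]]$mean_abundance
    s <- sum(prof[config$provocative_otus]) / sum(prof)
    EB2 <- s * (c0 * s + 1) / (c0 + 1)  # second moment of Beta(c0*s, c0*(1-s))
    EA <- EA + w[[g]] * ET * s
    EA2 <- EA2 + w[[g]] * ET2 * EB2
  }
  var_a <- EA2 - EA^2
  config$sigma * sqrt(r_squared / (1 - r_squared)) / sqrt(var_a)
}
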