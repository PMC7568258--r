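# Composite ileum histopathology rubric and the five-marker pathology panel.
#
# Five appraisals are binned to subscores and summed to an overall score in
# [0, 10]: crypt apoptosis (0/1), Paneth cell incidence (0..2 by halves),
# crypt density (0..2), inflammation foci (0..2) and inflammation intensity
# (0..3). Published bin edges look like rounded empirical cut points and
# leave small gaps (e.g. 0.33-0.34, 39-39.1); each gap is closed by extending
# the healthier-adjacent bin so the bins partition the whole input domain.
# Inputs beyond the worst printed bin clamp to that bin's subscore.

INTENSITY_LEVELS <- c("none", "small_abscess", "large_abscess", "erosion")

#' Subscore: crypt apoptosis
#'
#' @param x Apoptotic figures per crypt (>= 0).
#' @return 1 where `x` is strictly greater than 0.1, else 0.
#' @export
score_apoptosis <- function(x) {
  stopifnot(all(x >= 0))
  as.numeric(x > 0.1)
}

#' Subscore: Paneth cell incidence
#'
#' Fraction of crypts containing Paneth cells; lower incidence is worse.
#' Bins (closed at the healthier edge): \[0.8, 1\] -> 0; \[0.6, 0.8) -> 0.5;
#' \[0.34, 0.6) -> 1; \[0.15, 0.34) -> 1.5; \[0, 0.15) -> 2.
#'
#' @param f Fraction in \[0, 1\].
#' @return Subscore in \{0, 0.5, 1, 1.5, 2\}.
#' @export
score_paneth <- function(f) {
  stopifnot(all(f >= 0), all(f <= 1))
  ifelse(f >= 0.8, 0,
  ifelse(f >= 0.6, 0.5,
  ifelse(f >= 0.34, 1,
  ifelse(f >= 0.15, 1.5, 2))))
}

#' Subscore: crypt density
#'
#' Crypts per 10x field (one side); lower density is worse. Bins:
#' >= 39.1 -> 0; \[33.6, 39.1) -> 1; < 33.6 -> 2 (values below the worst
#' printed bin clamp to 2).
#'
#' @param d Crypts per 10x field (>= 0).
#' @return Subscore in \{0, 1, 2\}.
#' @export
score_density <- function(d) {
  stopifnot(all(d >= 0))
  ifelse(d >= 39.1, 0, ifelse(d >= 33.6, 1, 2))
}

#' Subscore: inflammation foci
#'
#' Inflammation foci per 10x field (both sides). Bins: 0 -> 0;
#' (0, 0.2\] -> 1; > 0.2 -> 2 (values above the worst printed bin clamp
#' to 2). Any positive focus count scores at least 1.
#'
#' @param f Foci per field (>= 0).
#' @return Subscore in \{0, 1, 2\}.
#' @export
score_foci <- function(f) {
  stopifnot(all(f >= 0))
  ifelse(f == 0, 0, ifelse(f <= 0.2, 1, 2))
}

#' Subscore: inflammation intensity
#'
#' Peak damage observed in the section: none -> 0, small crypt abscesses ->
#' 1, large abscesses -> 2, epithelial erosion/ulceration -> 3.
#'
#' @param g Character vector with values among `"none"`, `"small_abscess"`,
#'   `"large_abscess"`, `"erosion"`.
#' @return Subscore in \{0, 1, 2, 3\}.
#' @export
score_intensity <- function(g) {
  g <- as.character(g)
  bad <- setdiff(unique(g), INTENSITY_LEVELS)
  if (length(bad)) {
    stop("unknown intensity grade: ", paste(bad, collapse = ", "))
  }
  c(none = 0, small_abscess = 1, large_abscess = 2, erosion = 3)[g]
}

.check_histology <- function(obs) {
  obs <- as.data.frame(obs, stringsAsFactors = FALSE)
  req <- c("apoptosis_per_crypt", "paneth_fraction", "crypt_density",
           "foci_per_field", "intensity_grade", "exfoliation_fraction",
           "abscesses_per_field")
  miss <- setdiff(req, names(obs))
  if (length(miss)) {
    stop("histology observations missing column(s): ",
         paste(miss, collapse = ", "))
  }
  fracs <- c("paneth_fraction", "exfoliation_fraction")
  for (f in fracs) {
    if (any(obs[[f]] < 0 | obs[[f]] > 1)) {
      stop(f, " must lie in [0, 1]")
    }
  }
  counts <- c("apoptosis_per_crypt", "crypt_density", "foci_per_field",
              "abscesses_per_field")
  for (f in counts) {
    if (any(obs[[f]] < 0)) stop(f, " must be non-negative")
  }
  obs
}

#' Composite pathology score from raw histology observations
#'
#' Applies the five subscore rubrics and sums them into the overall score;
#' the overall score lies in \[0, 10\] and is a multiple of 0.5.
#'
#' @param obs Data frame of per-mouse histology observations with columns
#'   `apoptosis_per_crypt`, `paneth_fraction`, `crypt_density`,
#'   `foci_per_field`, `intensity_grade`, `exfoliation_fraction`,
#'   `abscesses_per_field`, and optionally `sample_id`.
#' @return Data frame of subscores (`apoptosis_sub`, `paneth_sub`,
#'   `density_sub`, `foci_sub`, `intensity_sub`) and their sum `overall`,
#'   one row per mouse, carrying `sample_id` when present in `obs`.
#' @export
#' @examples
#' overall_score(data.frame(
#'   apoptosis_per_crypt = 0.2, paneth_fraction = 0.5, crypt_density = 30,
#'   foci_per_field = 0.1, intensity_grade = "small_abscess",
#'   exfoliation_fraction = 0.2, abscesses_per_field = 0.5))
overall_score <- function(obs) {
  obs <- .check_histology(obs)
  subs <- data.frame(
    apoptosis_sub = score_apoptosis(obs$apoptosis_per_crypt),
    paneth_sub    = score_paneth(obs$paneth_fraction),
    density_sub   = score_density(obs$crypt_density),
    foci_sub      = score_foci(obs$foci_per_field),
    intensity_sub = unname(score_intensity(obs$intensity_grade))
  )
  subs$overall <- rowSums(subs)
  if ("sample_id" %in% names(obs)) {
    subs <- cbind(sample_id = obs$sample_id, subs)
  }
  subs
}

#' Direction convention of the five pathology markers
#'
#' @return Named logical vector, `TRUE` where a larger marker value means
#'   worse pathology. Only the Paneth cell fraction points the other way.
#' @export
marker_directions <- function() {
  c(overall_score = TRUE, exfoliation_fraction = TRUE,
    paneth_fraction = FALSE, abscesses_per_field = TRUE,
    apoptosis_per_crypt = TRUE)
}

#' Assemble the five-marker pathology panel
#'
#' The correlation screen uses five markers per mouse: the overall
#' composite score, the fraction of crypts with exfoliation (anoikis), the
#' fraction of crypts with Paneth cells, crypt abscesses per field, and
#' apoptotic figures per crypt. Direction flags are fixed by
#' [marker_directions()].
#'
#' @param obs Histology observations as for [overall_score()].
#' @param subs Optional precomputed output of [overall_score()]; computed
#'   from `obs` when omitted.
#' @return Object of class `marker_panel`: a data frame with one row per
#'   mouse and the five marker columns (plus `sample_id` when present),
#'   with the direction flags attached as attribute `"directions"`.
#' @export
marker_panel <- function(obs, subs = overall_score(obs)) {
  obs <- .check_histology(obs)
  stopifnot(nrow(subs) == nrow(obs))
  panel <- data.frame(
    overall_score        = subs$overall,
    exfoliation_fraction = obs$exfoliation_fraction,
    paneth_fraction      = obs$paneth_fraction,
    abscesses_per_field  = obs$abscesses_per_field,
    apoptosis_per_crypt  = obs$apoptosis_per_crypt
  )
  if ("sample_id" %in% names(obs)) {
    panel <- cbind(sample_id = obs$sample_id, panel)
  }
  attr(panel, "directions") <- marker_directions()
  class(panel) <- c("marker_panel", "data.frame")
  panel
}

#' Read per-mouse histology observations from CSV
#'
#' @param path CSV with one row per mouse and the columns listed under
#'   [overall_score()].
#' @return Validated data frame of observations.
#' @export
read_histology <- function(path) {
  .check_histology(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a marker panel from CSV
#'
#' @param path CSV with the five marker columns (and optionally
#'   `sample_id`), e.g. as written by [run_simulate()] or [run_score()].
#' @return A `marker_panel` object.
#' @export
read_marker_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- names(marker_directions())
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("marker panel missing column(s): ", paste(miss, collapse = ", "))
  }
  panel <- df[, intersect(c("sample_id", need), names(df)), drop = FALSE]
  attr(panel, "directions") <- marker_directions()
  class(panel) <- c("marker_panel", "data.frame")
  panel
}
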