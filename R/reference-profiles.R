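# Built-in study reference: published group-mean relative abundances (percent
# of classified reads) of the 24 ileal OTUs for the Splenda-control DKO group,
# the non-DKO littermates and the three antibiotic-treated DKO groups, plus the
# published sign-harmonized mean pathology correlation per OTU. Values are
# group means, not per-mouse data.

.reference_rows <- function() {
  # otu, splenda, nondko, metronidazole, vancomycin, streptomycin, pathology_r
  list(
    list("Lactobacillus",        44.6,   39.54,  55.97, 43.4,    1.77,    0.506),
    list("Clostridiaceae-1",     26.37,  25.05,  12.8,   0.1,    0.11,    0.455),
    list("Ureaplasma",            6.3,    0.64,   2.19,  0.107, 32.38,   -0.294),
    list("Sporacetigenium",       3.76,   0.68,   0.1,   0.1,    0.1,     0.343),
    list("Bacteroides",           1.81,   0.45,   0.1,   0.349,  4.4,    -0.227),
    list("Helicobacter",          1.22,   0.14,   0.11,  0.11,   0.17,    0.378),
    list("Escherichia/Shigella",  0.949,  0.11,  10.62, 44.9,    0.1,    -0.224),
    list("Parasutterella",        0.656,  0.46,   6.12,  1.23,  11.73,   -0.266),
    list("Streptococcus",         0.507,  0.26,   0.33,  0.1,    0.133,   0.403),
    list("Turicibacter",          0.477,  0.32,   0.2,   0.1,    0.1,     0.308),
    list("Dorea",                 0.465,  0.34,   0.1,   0.1,    0.113,   0.088),
    list("Staphylococcus",        0.417,  1.34,   0.14,  0.19,   0.159,   0.144),
    list("Roseburia",             0.39,   0.1,    0.1,   0.1,    0.1,     0.085),
    list("Barnesiella",           0.33,   8.33,   0.348, 0.1,    1.4,    -0.178),
    list("Lachnospiraceae",       0.266,  0.27,   0.1,   0.1,    0.104,   0.183),
    list("Pasteurellaceae",       0.26,   0.1,    0.1,   0.1,    0.1,     0.435),
    list("Alistipes",             0.21,   0.28,   0,     0,      0.001,   0.174),
    list("Ruminococcaceae",       0.19,   0.44,   0.1,   0.1,    0.1,     0.139),
    list("Allobaculum",           0.16,   0.03,   0.07,  0,     20.63,   -0.314),
    list("Desulfovibrio",         0.11,   1.31,   0,     0,      0.0002,  0.175),
    list("Porphyromonadaceae",    0.11,   1.17,   0,     0,      0.58,   -0.299),
    list("Bifidobacteriaceae",    0.11,   0.016,  5.86,  0,      0.79,    0.099),
    list("Enterococcus",          0.1,    0.01,   2.65,  0.00065, 0.044,  0.044),
    list("Akkermansia",           0,      0.0003, 0.25,  0,      0,       0.122)
  )
}

#' Published group-mean abundance reference for the DKO antibiotic study
#'
#' Returns the published mean relative abundances (percent of classified
#' reads) of the 24 study OTUs in the five experimental groups -- Splenda
#' control DKO, non-DKO littermates, and metronidazole-, vancomycin- and
#' streptomycin-treated DKO mice -- together with the published
#' sign-harmonized mean pathology correlation coefficient per OTU
#' (positive: higher abundance goes with more pathology).
#'
#' Column totals fall short of 100 because only classified reads contribute;
#' the per-column totals range from about 75 to 98 percent.
#'
#' @return A data frame with columns `otu`, `splenda`, `nondko`,
#'   `metronidazole`, `vancomycin`, `streptomycin` (percent) and
#'   `pathology_r` (dimensionless, in \[-1, 1\]), one row per OTU, ranked by
#'   Splenda abundance.
#' @seealso [reference_profile()] to extract one group as a
#'   [group_profile()]; [simulation_config()] which uses these profiles as
#'   generative defaults.
#' @export
#' @examples
#' ref <- reference_profiles()
#' head(ref)
#' sum(ref$splenda)  # total classified percent in the Splenda control group
reference_profiles <- function() {
  rows <- .reference_rows()
  data.frame(
    otu           = vapply(rows, function(r) r[[1]], character(1)),
    splenda       = vapply(rows, function(r) r[[2]], numeric(1)),
    nondko        = vapply(rows, function(r) r[[3]], numeric(1)),
    metronidazole = vapply(rows, function(r) r[[4]], numeric(1)),
    vancomycin    = vapply(rows, function(r) r[[5]], numeric(1)),
    streptomycin  = vapply(rows, function(r) r[[6]], numeric(1)),
    pathology_r   = vapply(rows, function(r) r[[7]], numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Extract one study group as a group profile
#'
#' @param group One of `"splenda"`, `"nondko"`, `"metronidazole"`,
#'   `"vancomycin"`, `"streptomycin"`.
#' @return A [group_profile()] object (group label + named mean-abundance
#'   vector in percent).
#' @export
#' @examples
#' total_classified(reference_profile("splenda"))
reference_profile <- function(group = c("splenda", "nondko", "metronidazole",
                                        "vancomycin", "streptomycin")) {
  group <- match.arg(group)
  ref <- reference_profiles()
  group_profile(group, setNames(ref[[group]], ref$otu))
}

#' Study group sizes used for microbiome analysis
#'
#' Eight DKO mice per treatment group (Splenda control and the three
#' antibiotics) and six non-DKO littermates were profiled.
#'
#' @return Named integer vector of per-group sample counts.
#' @export
reference_group_sizes <- function() {
  c(splenda = 8L, metronidazole = 8L, vancomycin = 8L, streptomycin = 8L,
    nondko = 6L)
}
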