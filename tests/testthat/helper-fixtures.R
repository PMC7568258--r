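# Fixtures are built in code: small hand-sized tables plus the built-in
# group-mean reference rendered as an abundance table.

# abundance table with one sample per study group, each equal to the
# published group-mean profile
reference_fixture <- function() {
  ref <- reference_profiles()
  groups <- c("splenda", "nondko", "metronidazole", "vancomycin",
              "streptomycin")
  values <- t(vapply(groups, function(g) ref[[g]], numeric(nrow(ref))))
  colnames(values) <- ref$otu
  rownames(values) <- paste0(groups, "_1")
  meta <- data.frame(
    sample_id = rownames(values),
    genotype = ifelse(groups == "nondko", "nonDKO", "DKO"),
    treatment = ifelse(groups == "nondko", "splenda", groups),
    group = groups,
    stringsAsFactors = FALSE
  )
  abundance_table(values, meta)
}

# tiny generic table: n samples x named OTU columns
toy_table <- function(values, genotype = NULL, treatment = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("s%02d", 1:n)
  meta <- data.frame(
    sample_id = rownames(values),
    genotype = if (is.null(genotype)) rep("DKO", n) else genotype,
    treatment = if (is.null(treatment)) rep("splenda", n) else treatment,
    stringsAsFactors = FALSE
  )
  abundance_table(values, meta)
}

random_table <- function(n_samples, n_otus, max_val = 10) {
  values <- matrix(round(stats::runif(n_samples * n_otus, 0, max_val), 3),
                   n_samples, n_otus,
                   dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                   sprintf("otu%02d", seq_len(n_otus))))
  toy_table(values)
}

random_histology <- function(n) {
  data.frame(
    apoptosis_per_crypt = stats::runif(n, 0, 0.6),
    paneth_fraction = stats::runif(n),
    crypt_density = stats::runif(n, 20, 50),
    foci_per_field = stats::runif(n, 0, 1),
    intensity_grade = sample(c("none", "small_abscess", "large_abscess",
                               "erosion"), n, replace = TRUE),
    exfoliation_fraction = stats::runif(n, 0, 0.5),
    abscesses_per_field = stats::runif(n, 0, 3),
    stringsAsFactors = FALSE
  )
}
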