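---
title: "Methods: from OTU abundances to candidate verdicts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from OTU abundances to candidate verdicts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otuTriage)
```

# The analysis problem

otuTriage implements the downstream analysis for a mouse ileitis study
design: Gpx1/2 double-knockout (DKO) mice develop ileal inflammation
whose severity depends on the gut microbiota, and antibiotic treatments
(metronidazole, vancomycin, streptomycin, against a Splenda vehicle
control) perturb both the 16S OTU community and the pathology. The goal
is to triage which OTUs are *provocative* (abundance tracks with worse
pathology) and which look *beneficial or opportunistic* (enriched in
cured or control mice), using three independent lines of evidence.

The data objects are small by genomics standards — tens of mice, a few
dozen genus/family-level OTUs — so every method here is chosen for
stability at small n, not for throughput.

# Abundance tables

Abundances are *percent of classified reads* per sample. Rows need not
sum to 100 (unclassified reads are excluded), but a row total above 100
(plus a small tolerance) is rejected at construction. `abundance_table()`
couples the numeric matrix to per-sample metadata (genotype, treatment,
optional sex and group) and validates both. `read_mothur_shared()`
converts raw count tables from the mothur *shared* format to percent.

`filter_otus()` applies the study's reporting filter (strictly above
0.5% in at least one sample by default). `core_microbiota()` encodes the
rule used to call the disease-independent core: an OTU is core when its
DKO and non-DKO group means differ by strictly less than 2-fold, its
differential p-value exceeds 0.09, and both group means are at least
0.2%. The mean floor keeps trace OTUs sitting at the reporting floor —
whose fold ratio is uninformative — out of the core. On the built-in
reference profiles this returns eight OTUs:

```{r core}
core_microbiota(reference_profile("splenda"), reference_profile("nondko"))
```

# Pathology scoring

`overall_score()` implements a composite rubric over five subscores:

* apoptotic nuclei per crypt (0 or 1; above 0.1 scores 1),
* Paneth-cell incidence, the fraction of crypts with Paneth cells
  (0–2 in steps of 0.5; full incidence scores 0, loss scores up),
* crypt density per unit length (0–2),
* exfoliation/inflammation foci per field (0–2),
* lesion intensity grade: none, small abscess, large abscess, erosion
  (0–3).

Bins are half-open and closed at the healthier edge; observations worse
than the worst printed bin clamp to the maximal subscore, so the overall
score is bounded in [0, 10] and is always a multiple of 0.5. Monotonicity
(worsening any observation never lowers the score) and boundedness are
enforced by property tests rather than assumed.

`marker_panel()` assembles the five per-mouse markers used in the
correlation screen: overall score, exfoliation fraction, Paneth
fraction, crypt abscesses per field, and apoptosis per crypt.
`marker_directions()` records the sign convention: only the Paneth
fraction points toward health, so its correlations are flipped before
averaging ("sign harmonization").

# Ordination

Community distances use the quantitative (Ružička) Jaccard distance,
`1 - sum(pmin(x, y)) / sum(pmax(x, y))`, which stays in [0, 1], is a
metric, and reduces to binary Jaccard on presence/absence calls
(`mode = "binary"`, presence strictly above 0.5%). Two all-zero samples
are defined to be at distance 0.

`pcoa()` embeds the distance matrix by classical metric scaling
(`stats::cmdscale`). Negative eigenvalues — expected for non-Euclidean
distances like Jaccard — are reported, not corrected; explained-variance
fractions use the positive part of the spectrum only. For
Euclidean-consistent inputs the embedding reproduces the distances to
numerical precision, which the test suite checks at 1e-8.

# Differential abundance

Percent abundances are floored at 0.1% (the study's detection floor) and
log2-transformed. Each OTU gets a two-sample comparison with an
empirical-Bayes moderated t-statistic: per-OTU variances are shrunk
toward a scaled-F prior fit across OTUs by method of moments on the log
variances (`fit_variance_prior()`, including the inverse-trigamma Newton
iteration; when the observed spread is no larger than the sampling
component the prior degrees of freedom collapse to infinity and all
OTUs share the prior variance). The posterior variance is
`(d0*s0^2 + d*s^2) / (d0 + d)` with `d + d0` degrees of freedom. This is
deliberately the same model family as limma's `eBayes`; the test suite
cross-checks both the prior fit and the statistics against limma to
1e-6/1e-8 without using limma in the implementation.

Multiplicity is controlled by Benjamini–Hochberg FDR (`bh_fdr()`, a thin
wrapper over `stats::p.adjust`). A call requires both a fold change of
at least 1.2 on floored group means and q ≤ 0.05. The fold convention —
`floored_mean_ratio()` — is shared with the triage module so both report
the same effect sizes.

# Candidate triage

`triage_otus()` combines three signals per OTU:

1. **Cured-vs-sick extremes** (`stratify_extremes()`,
   `cured_sick_screen()`): DKO mice with overall score ≤ 1 are "cured",
   ≥ 5 are "sick". The screen reports the floored cured/sick abundance
   ratio (below 1 suggests provocative) and a pairwise t-test p-value.
   Bonferroni correction is applied over the *candidate* family only —
   OTUs whose pairwise p ≤ 0.05 — mirroring a post-test adjustment;
   non-candidates get `NA`.
2. **Marker correlations** (`marker_correlation_panel()`): Pearson
   correlation of each OTU's abundance with each of the five markers
   across all DKO mice, sign-harmonized and averaged. Degenerate pairs
   (zero variance) are recorded as r = 0 with a flag.
   `combined_correlation()` sums several OTUs' abundances first;
   `dilution_adjust()` renormalizes a target OTU against a diluting OTU
   (`target / (100 - diluter) * 100`) before correlating.
3. **DKO vs non-DKO shift**: the differential screen between Splenda
   DKO mice and non-DKO littermates; an expansion in diseased mice
   counts toward provocative only when the call is significant.

`consensus_classify()` requires at least two concordant signals:
two pathology-positive signals yield `provocative`, two negative ones
`beneficial_or_opportunistic`, anything else `indeterminate`.

# Synthetic studies and calibration

`make_study()` generates a full synthetic study for end-to-end
validation. Compositions are Dirichlet draws with
`alpha = concentration * profile / sum(profile)` per group
(concentration 50 by default, chosen so that within-group scatter is of
the same order as the real per-mouse variation around group means), and
row totals are uniform on [75, 98] — the observed range of classified
fractions. The default design matches the study: 8 DKO mice per
treatment group plus 6 non-DKO littermates (38 × 24).

Pathology follows a latent-severity model: with `A` the summed percent
abundance of the designated provocative OTUs (Lactobacillus and
Clostridiaceae-1 by default),

```
l = beta0 + beta1 * A + Normal(0, sigma),   score = round(clip(l, 0, 10) * 2) / 2
```

Defaults `beta0 = 1.2`, `beta1 = 0.07`, `sigma = 0.8` put the Splenda
control mean score in the observed severe range while letting the
antibiotic groups spread downward. The four remaining markers are
saturating logistic links of `l` with small Gaussian noise
(`marker_sigma = 0.03`), so all five markers are monotone in severity —
the property the correlation screen assumes.

`calibrate_score_slope()` inverts the model analytically: using the
Dirichlet aggregation property, the summed provocative abundance within
a group is Beta-distributed, so its mixture variance over the DKO groups
has a closed form, and the slope needed for a target latent R² is
`beta1 = sigma * sqrt(R2 / (1 - R2)) / sd(A)`. The acceptance suite
verifies that the calibrated slope recovers R² = 0.5 within ±0.15 over
100 replicates at the design size.

# Problem sizes and limitations

All methods are tuned for the study scale: up to a few hundred samples
and OTUs; the property tests run thousands of small cases in minutes.
Known limitations:

* The moderated t assumes approximate log-normality of floored percent
  abundances; heavily zero-inflated OTUs sit at the floor and carry no
  information (they are dropped from the variance prior with a warning).
* Compositional effects are handled only via the explicit dilution
  adjustment, not by a full log-ratio framework.
* PCoA negative eigenvalues are reported, not corrected; axis
  interpretation should check `explained` and `all_eigenvalues`.
* The consensus rule is a screen, not an inference procedure: verdicts
  are candidates for follow-up, not causal claims.
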