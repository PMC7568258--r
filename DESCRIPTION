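Package: otuTriage
Title: Triage of Ileal Microbiota Candidates Against Ileitis Severity in
    Gpx1/2 Double-Knockout Mice
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis pipeline linking ileal 16S OTU
    relative-abundance profiles to ileitis severity in glutathione
    peroxidase 1/2 double-knockout (Gpx1/2-DKO) mice. Provides a composite
    histopathology scoring rubric and five-marker pathology panel,
    abundance-table import, filtering and core-microbiota summaries,
    quantitative (Ruzicka) and binary Jaccard ordination by principal
    coordinates, an empirical-Bayes moderated t-test screen for
    differential abundance with Benjamini-Hochberg FDR control, a
    three-way candidate triage (cured-versus-sick extreme screen,
    sign-harmonized abundance-pathology correlation panel, DKO versus
    non-DKO shifts) with consensus classification of OTUs as provocative
    or beneficial/opportunistic, and a Dirichlet synthetic-community
    generator with linked pathology markers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    vegan,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
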