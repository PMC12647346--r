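Package: gbacor
Title: Guilt-by-Association Correlation Analysis of Pan-Cancer Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for guilt-by-association (GBA) analysis of wide
    protein-abundance matrices: zero imputation of missing intensities,
    all-vs-all Spearman co-abundance matrices, descending-ranked partner
    queries for a bait protein, validation of correlation coherence against
    GO-term sets and synthetic-lethal pair lists (median-shift statistics),
    protein-panel correlation/abundance/sparsity summaries, and a
    replicate-based differential-abundance (volcano) contrast. Includes a
    latent-factor synthetic-cohort generator with tunable module structure
    and abundance-dependent missingness so every stage can be exercised and
    calibrated without external downloads, plus a small pipeline driver and
    command-line wrapper emitting plot-ready TSV outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
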