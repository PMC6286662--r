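Package: ednacomp
Title: Composite Versus Grab Sampling Analysis for eDNA Metabarcoding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparing composite and grab water sampling schemes in
    environmental DNA (eDNA) metabarcoding surveys. Implements a modified
    lowest-common-ancestor (LCA) taxonomic assigner for BLAST-style alignment
    hit tables with bit-score windowing, identity-based rank demotion and
    watershed-constrained re-assignment; operational-taxon count-table
    filtering rules (run-wide minimum counts, amplicon length windows,
    cross-talk censoring, rank collapsing, counts-per-million normalization);
    community comparison statistics (Morisita dissimilarity, rarefaction
    richness with standard errors, distance-to-centroid dispersion tests,
    taxon detection rates with sample-parity trimming); relative-abundance
    precision analysis for two focal taxa (variance F-test, two-way ANOVA,
    time correlations); compositional ordination (log-ratio transform,
    correlation PCA, Spearman matrices); and a synthetic stream-scenario
    generator emulating clumped eukaryotic versus near-Poisson bacterial eDNA
    under composite and grab sampling with storage effects and sequencer
    cross-talk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
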