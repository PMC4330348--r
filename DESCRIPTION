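Package: silacnet
Title: Weighted Correlation Network Analysis of Super-SILAC Peptide
    Pulldown Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for histone-tail peptide pulldown experiments
    quantified against a pooled (super-SILAC style) mixed reference. Reads
    protein-groups ratio tables, applies contaminant/decoy/ratio-count and
    missingness filters, builds a signed weighted correlation network with
    soft thresholding and topological overlap, cuts the resulting dendrogram
    into reader-complex modules with a deterministic adaptive tree cut,
    summarizes modules by eigenproteins and intramodular connectivity,
    computes module-versus-beads paired t statistics and per-protein outlier
    z-scores, and assembles bait-normalized immunoprecipitation networks.
    Includes a synthetic-data generator that plants protein complexes with
    condition-specific binding signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
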