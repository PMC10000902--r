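Package: ProteoformSim
Title: Simulating and Comparing Proteoform-Resolved Top-Down and
    Bottom-Up Proteomics Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic proteomes with proteoform structure
    (phosphorylation and proteolytic cleavage variants of canonical
    proteins) and simulates their measurement by the two standard
    quantitative proteomics platforms: gel-based top-down 2D-DIGE with a
    Cy2 internal standard, and gel-free bottom-up label-free shotgun
    LC-MS/MS with data-dependent acquisition.  Implements the statistics
    used to compare the platforms: raw-scale coefficients of variation
    over technical and biological replicates (with the log2-scale misuse
    demonstrated as a property), reproducibility accounting over matched
    entities, spot-level versus proteoform-summed Spearman rank
    correlation, lambda-phosphatase based phosphoproteoform
    classification, iBAQ and phosphopeptide stoichiometry ratios, and
    per-protein workload accounting.  Ships a curated two-platform spot
    catalog of the DU145 prostate carcinoma proteome as a worked
    reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    Biostrings
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
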