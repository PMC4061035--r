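Package: ovimetab
Title: Plasma NMR Metabolomics and Muscle Fibre Morphometry of the Ovine
    Callipyge Phenotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for 1D 1H NMR plasma
    metabolomics of Callipyge (NmatCpat) versus wild-type (NmatNpat) lambs,
    together with myofibre-type morphometry statistics. Provides a seeded
    synthetic cohort generator (metabolite concentrations with planted age
    and genotype effects, Lorentzian spectrum rendering, EDTA/water/urea
    artifacts and outlier modes), chemical-shift referencing, fixed-width
    spectral bucketing with exclusion windows, total-intensity normalization
    and Pareto scaling, NIPALS PCA with Hotelling T-squared outlier
    detection, PLS-DA and OPLS-DA with cross-validated Q2, permutation
    testing, CV-ANOVA and VIP, a Shapiro-Wilk-gated univariate stage with
    Benjamini-Hochberg correction, hypergeometric pathway enrichment with
    out-degree-centrality topology impact, and one-way ANOVA fibre-type
    summaries with s.e.d.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
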