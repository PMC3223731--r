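Package: ftsascreen
Title: Fluorescence Thermal-Shift Ligand Screening for Solute-Binding Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of fluorescence thermal-shift (differential
    scanning fluorimetry) ligand-binding screens for bacterial ABC-transporter
    solute-binding proteins. Provides a two-state van 't Hoff melt-curve
    simulator with ligand-coupled stabilization and instrument profiles, a
    derivative-based Tm caller with quality control, ligand-pool construction
    and two-step pooled/deconvolution screen planning, delta-Tm binding
    classification at a 2 degree threshold, and evidence-based tiering of
    functional assignments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Proteomics, Cheminformatics, QualityControl
RoxygenNote: 7.3.3
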