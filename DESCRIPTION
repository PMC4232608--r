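Package: ercdyn
Title: Asymmetric Segregation of DNA Circles and Nuclear Pores in Ageing Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for studying the retention of
    extrachromosomal DNA circles (ERCs and non-centromeric plasmids) in
    budding yeast mother cells and its consequences for nuclear pore
    complex (NPC) inheritance and replicative ageing.  Provides the
    propagation-frequency (pf) estimator for telophase segregation
    assays, pedigree and half-sectored-colony retention statistics,
    FLIP/FRAP photobleaching kinetics with time-to-fraction statistics
    and the bud-neck barrier index, nucleus-image and rim-profile
    quantification (NPC cap intensity, percent-to-mother, peak-aligned
    enrichment, particle-track speeds, age trends), a stochastic
    mother-cell simulator of ERC formation, doubling, asymmetric
    retention, NPC co-retention and replicative lifespan, and seeded
    synthetic-data generators that emulate every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    survival,
    multcomp,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
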