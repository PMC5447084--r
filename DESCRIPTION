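Package: meconet
Title: Molecular Ecological Networks for Soil Microbiome and Functional Gene Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring and characterising co-occurrence networks from
    soil microbiome surveys that combine amplicon (OTU) count tables with
    functional gene array (GeoChip-style) signal intensities. Implements the
    standard preprocessing steps for such data (rarefaction, prevalence
    filtering, signal-to-noise filtering, lnMR normalisation), alpha-diversity
    and gene-set overlap summaries, random-matrix-theory (RMT) threshold
    selection for phylogenetic molecular ecological networks with Zi-Pi node
    role classification, and CoNet-style ensemble association inference with a
    ReBoot permutation-renormalisation null and Brown's method for combining
    dependent p-values. A synthetic data generator with planted correlation
    modules and taxa-function couplings supports end-to-end validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    vegan,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
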