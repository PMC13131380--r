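Package: ipgblup
Title: Indirect Genomic Predictions from Single-Step GBLUP under Genotyping Errors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how genotyping errors in young selection
    candidates degrade indirect genomic predictions (IP) computed from SNP
    effects back-solved from single-step GBLUP (ssGBLUP) breeding values.
    Includes a forward-in-time breeding-program simulator (bottlenecked
    historical population, random-mating expansion, truncation selection on
    pedigree-BLUP EBV with assortative mating), pedigree and genomic
    relationship machinery (Henderson's A-inverse with Meuwissen-Luo
    inbreeding, VanRaden G, tuning and blending, the APY sparse inverse,
    and the H-inverse genotyped-block correction), a single-trait
    animal-model ssGBLUP solver, SNP-effect back-solving and indirect
    prediction with configurable genotyping-error injection, and the
    evaluation statistics (correlations, dispersion, RMSE, standardized
    bias, variance ratios) aggregated across simulation replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
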