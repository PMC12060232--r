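Package: rilqtl
Title: QTL and Epistasis Scans for Ancestry-Window Genotyped Recombinant Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Additive single-locus QTL genome scans, two-locus epistasis
    scans, permutation-based genome-wide significance, Fisher
    combined-probability meta-analysis, and simulation-based power analyses
    for biparental recombinant inbred line (RIL) panels genotyped as diploid
    ancestry dosages in genomic windows. Includes a calibrated synthetic-panel
    generator emulating Drosophila melanogaster RIL panels (megabase-scale
    ancestry tracts, residual heterozygosity, ancestry skew), window-level
    genotype summarization and filtering, genotype-by-environment reaction
    norm tests, and Hudson F_ST window scans with per-arm outlier flagging.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr
Config/testthat/edition: 3
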