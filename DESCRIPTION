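Package: venompsc
Title: Protein Score Chromatograms for Nanofractionation Venomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for high-resolution nanofractionation
    venomics. Maps serpentine-collected 384-well plate fractions to liquid
    chromatography retention times, merges per-well bottom-up protein search
    results into a retention-time-sorted table, builds Protein Score
    Chromatograms (PSCs), Sequence Coverage Chromatograms and the Total
    Protein Chromatogram, detects and integrates PSC peaks for
    semiquantitative toxin-family composition, and correlates PSC peaks with
    intact-mass extracted ion chromatograms and UV traces to flag
    isoform and post-translational-modification candidates. Includes a
    synthetic venom simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
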