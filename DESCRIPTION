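Package: extether
Title: Annotation and Semi-Quantification of Extended Archaeal Ether Lipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructive elemental-formula and monoisotopic-mass modelling of
    archaeal ether lipids (archaeols, glycerol dialkyl/trialkyl glycerol
    tetraethers and their isoprenoid-extended homologs), in-silico MS2
    fragmentation and spectrum annotation, homolog-series (mass-ladder)
    detection in high-resolution MS1 feature tables, and injection-standard
    semi-quantification with class-specific response factors. Includes a
    synthetic-data generator for feature tables, MS2 spectra and calibration
    files so the full annotation pipeline can be exercised without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
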