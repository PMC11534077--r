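Package: ancestrypaint
Title: Visualization of Global and Local Ancestry from RFMIX2 Output
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts the numerical output of the RFMIX2 local-ancestry
    inference software into graphical summaries: per-individual global
    ancestry stacked bar plots (Global Ancestry Painting), per-haplotype
    chromosome karyograms (Local Ancestry Painting), and locus-level
    ancestry composition reports. Includes readers and writers for the
    RFMIX2 '.rfmix.Q' and '.msp.tsv' formats, BED export of ancestry
    tracts, and a synthetic RFMIX2-output generator with known ground
    truth so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
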