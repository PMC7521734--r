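Package: msbarcode
Title: Microsatellite Band-Pattern Barcoding for Strain Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microsatellite (SSR) strain barcoding from PCR band
    patterns: canonical tandem-repeat motif handling and repeat-tract
    detection, in-silico PCR amplicon prediction from primer pairs,
    gel-resolution-aware band clustering and strain fingerprints, a four-level
    pairwise informativeness classifier with panel-wide discrimination
    summaries, strain identification against a reference panel, and a seeded
    simulator of diploid strain panels (locus duplication, primer-site loss,
    flank indels, polymerase-slippage stutter and somatic mosaicism) so the
    whole pipeline can be exercised without external data. Developed around
    the three-locus Hydra strain-typing design (ms-c25145, ms-AIP, ms-DMTF1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
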