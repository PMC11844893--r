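Package: specid
Title: Library-Based Compound Identification Scoring for GC-EI-MS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for library-based identification of electron-ionization
    mass spectra from gas chromatography. Implements the Identity, Reverse,
    Similarity and Hybrid (neutral-loss) spectral match factors on the
    standard 0-999 scale, Kovats retention-index score penalization,
    confidence corrections based on hit-list Probability and a Compound
    Ubiquity Index, and a bounded composite score that combines them.
    Includes NIST MSP text format input/output, spectrum cleanup
    (base-peak normalization, calibrant removal, abundance thresholding),
    molecular-mass estimation for trimethylsilyl-derivatized spectra,
    median-relative-abundance identifiability triage, a search pipeline
    with tab-separated hit-list output, and a synthetic fixture generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
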