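Package: xldoublet
Title: Stub-Doublet Detection and MS3-Trigger Emulation for MS-Cleavable
    Crosslinkers
Version: 0.1.0
Authors@R: person("xldoublet", "developers", role = c("aut", "cre"),
    email = "xldoublet@example.org")
Description: Computational core for analysing MS-cleavable crosslinker
    fragmentation in crosslinking mass spectrometry. Models crosslinker
    stub-fragment masses from elemental compositions (UVPD- and
    CID-cleavable reagents), detects signature stub-pair doublets in
    centroided MS2 peak lists with hydrogen-shift delta-mass variants,
    emulates MS3 precursor selection with an exclusion-window filter,
    annotates spectra with backbone and stub fragments, and computes the
    orthogonality, prevalence, sensitivity and specificity statistics used
    to compare cleavable crosslinkers. Includes a seeded ground-truth
    generator of crosslinked, linear and crosslinker-modified synthetic
    spectra, and MGF read/write.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
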