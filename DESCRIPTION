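Package: mfoct
Title: Multifunctional Optical Coherence Tomography Analysis of Skin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of complex-valued swept-source
    optical coherence tomography (OCT) acquisitions of skin, with three
    analysis arms: depth-resolved attenuation via the OCT signal slope
    (OCTSS) over the dermis, optical coherence elastography (OCE) wave-speed
    estimation from phase-sensitive M-B-mode scans, and correlation-mapping
    optical coherence angiography (cm-OCA) with sub-pixel bulk-motion
    registration, SNR-aware noise masking, breathing-stripe suppression and
    vessel lumen measurement. Includes a synthetic complex-OCT phantom
    generator with known ground truth (speckle, layered attenuation,
    traveling surface waves, decorrelating vessels, bulk and breathing
    motion) so that every stage of the pipeline can be validated by
    parameter recovery, plus cohort-level aggregation and group statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    EBImage,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
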