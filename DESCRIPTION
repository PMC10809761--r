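Package: tracemid
Title: 13C Tracer Metabolomics of Amino Acids by CE-MS: Isotopologue
    Correction, Positional Isotopomers, and Carbon-Fixation Pathway
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stable-isotope (13C) tracer metabolomics of
    underivatized proteinogenic amino acids measured by capillary
    electrophoresis-mass spectrometry. Reads precursor- and fragment-level
    peak lists, annotates amino acids by accurate mass and migration time,
    extracts isotopologue areas, normalizes them to mass isotopomer
    distributions (MIDs), removes the natural 13C background (1.1% per
    carbon) by non-negative deconvolution, and resolves main-chain versus
    side-chain positional isotopomers from MS/MS fragment patterns. A
    carbon atom-transition network simulator predicts steady-state
    labeling under a tracer specification, and a deterministic fitting
    layer ranks carbon-fixation pathway hypotheses (Wood-Ljungdahl with
    incomplete or complete reductive TCA cycle) against corrected MIDs.
    A seeded synthetic-data generator emulates CE-MS peak lists for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
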