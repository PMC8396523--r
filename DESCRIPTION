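Package: mabquant
Title: Intact Antibody Proteoform Quantitation from Native LC-MS Runs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-quantitation of intact monoclonal-antibody proteoforms
    (glycoform pairs, C-terminal lysine variants, modification deltas)
    from native cation-exchange LC-MS MS1 data. Computes theoretical
    proteoform masses from elemental compositions, extracts and
    integrates per-proteoform ion current chromatograms, reports
    fractional abundances, galactosylation and glycoform-class quality
    attributes with t-based replicate confidence intervals, performs a
    simplified zero-charge deconvolution with glycosylation-pattern
    mass-shift detection, and ships a synthetic-run generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    mzR,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
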