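Package: digiwestr
Title: Bead-Based Multiplex Western Blot (DigiWest) Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for bead-based multiplex Western blots
    (DigiWest-style assays) as used to characterize extracellular-vesicle
    preparations. Reconstructs virtual gel lanes from color-coded bead
    median-fluorescence readouts, calibrates molecular weight from ladder
    anchors by piecewise log-linear interpolation, estimates and subtracts a
    baseline derived from empty-bead and secondary-antibody-only controls,
    detects antibody-specific peaks at their expected molecular weights and
    integrates them into accumulated fluorescence intensities (AFI), applies
    marker-acceptance criteria (minimum peak height, minimum AFI, molecular
    weight matching with a bounded shift, cross-sample shift consistency),
    and renders Western-blot mimics, SEC-fraction AFI heat maps, and
    concordance tables. Includes a synthetic-data generator that emits
    complete assay datasets with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
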