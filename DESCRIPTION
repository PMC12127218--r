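Package: prcf
Title: Processed-to-Raw Food Conversion Factors for Dietary Exposure Assessment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for converting processed-food consumption records into
    raw-commodity intake for dietary exposure assessment. Implements the
    reverse percentage-yield, partition-corrected, and component migration-rate
    derivations of processed-to-raw conversion factors (PRCFs), bundles a
    machine-readable reference table of 120 published factors with integrity
    validators, converts consumption diaries into raw-commodity equivalents
    (with optional chemical-specific migration-ratio substitution), computes
    total polyphenol content from Folin-Ciocalteu plate readings via a gallic
    acid standard curve, and generates synthetic study data with known ground
    truth. A command-line interface wires all components together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
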