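Package: splicecodes
Title: ACMG/AMP Evidence Codes for Variant Effects on RNA Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for interpreting sequence variants with respect to RNA
    splicing under the ACMG/AMP framework. Calibrates splice-prediction score
    thresholds against spliceogenicity truth data using likelihood ratios
    mapped to ACMG/AMP evidence strengths; classifies variant positions into
    splice-region categories (canonical dinucleotide, standard and minimal
    splice regions); applies a gene-configurable PVS1 loss-of-function
    decision tree with rescue-transcript logic and re-weighting from RNA
    splicing assay read-outs (including leaky and complex read-outs); assigns
    the splicing adaptations of PS1, PP3/BP4 and BP7 (including
    PVS1_Strength(RNA) and BP7_Strong(RNA)); and combines codes with
    mutual-exclusion bookkeeping. Includes a synthetic truth-set generator
    and deterministic fixtures so every component is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rtracklayer,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
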