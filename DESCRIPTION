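Package: tallpipe
Title: Genomic Lesion Calling, Integration, and Steroid-Inhibitor Synergy
    Analysis for Pediatric T-ALL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational chain used to
    dissect steroid resistance in pediatric T cell acute lymphoblastic
    leukemia: confidence calibration of somatic variant calls (ROC-based
    score thresholds for whole-genome calls; one-class Gaussian and
    axis-aligned decision-rule classifiers for targeted-exome calls),
    seven-criterion filtering of structural-variant breakpoint junctions
    with non-template nucleotide counting, array-CGH copy-number calling
    via the three-consecutive-probe two-standard-deviation rule, gene-level
    lesion integration with subtype, in vitro prednisolone LC50 and
    survival endpoints, and curve-shift combination-index synergy analysis
    of steroid-inhibitor mixtures. A synthetic-data module generates inputs
    with the statistical structure each stage assumes, so the whole
    pipeline is testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
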