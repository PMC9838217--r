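Package: selexat
Title: HT-SELEX K-mer Enrichment, Binding Isotherms and Domain Variant Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies transcription-factor binding specificity from HT-SELEX
    sequencing libraries by canonical k-mer read-containment counting, per-cycle
    fold-change enrichment, A/T-composition group summaries, top-motif overlap
    and one-mismatch position frequency matrices. Includes a deterministic
    synthetic SELEX experiment generator with a ground-truth affinity model for
    end-to-end validation, electrophoretic mobility shift assay (EMSA) band
    normalisation and hyperbolic binding-isotherm fitting, and protein-domain
    missense-variant depletion scoring (Vp, Vd/Vp) with a clinical-versus-
    population variant filter.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
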