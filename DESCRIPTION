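Package: delscreen
Title: DNA-Encoded Library Selection Analysis and Machine-Learning Hit Finding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, fully synthetic re-implementation of a
    DEL-ML hit-finding workflow: simulation of split-and-pool DNA-encoded
    library selections with planted ground-truth binders, decoding and
    UMI-deduplication of selection sequencing reads, disynthon-level
    enrichment statistics and five-class hit labeling, fingerprint-based
    random-forest and neural-network virtual screening ensembles,
    diversity-aware compound selection and hit expansion, and 1:1
    binding-model fitting (SPR kinetic and steady state, DSF, FP
    displacement) with selectivity-matrix normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    minpack.lm,
    ranger,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (obabel on PATH) for fingerprinting and
    molecular properties
Config/testthat/edition: 3
RoxygenNote: 7.3.3
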