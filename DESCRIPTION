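Package: gckmap
Title: Variant Activity Maps from Growth-Selection Deep Mutational Scans of Glucokinase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns pre/post-selection variant counts from a saturation-mutagenesis
    growth selection of human glucokinase (GCK) into rescaled activity scores
    (synonymous-median 1, nonsense-median 0) with Bayesian-regularized standard
    deviations and bootstrap confidence intervals. Includes ROC-based selection of
    clinical classification thresholds, conservation-profile comparisons from
    filtered multiple sequence alignments, a conformational equilibrium-shift
    score from paired per-conformation stability predictions, and a full
    synthetic-data generator (NNK codon library, activity-dependent growth,
    multinomial sequencing sampling, coupled two-conformation free-energy tables)
    so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
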