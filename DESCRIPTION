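Package: acpnet
Title: Hybrid Sequence and Physicochemical Classifier for Anticancer Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies anticancer peptides (ACPs) from amino-acid sequence
    alone by fusing two views of a peptide: a 35-dimensional manually
    engineered feature vector (pseudo amino acid composition, length, Shannon
    entropy, GRAVY hydropathy, molecular weight, and net charge at pH 10)
    processed by a dense network, and a learned per-residue embedding
    processed by a bidirectional LSTM. Provides FASTA data handling,
    feature extraction, model training with early stopping, prediction with a
    configurable decision threshold, confusion-matrix metrics with ROC/PR
    curves, a synthetic peptide generator with a plantable class signal for
    end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
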