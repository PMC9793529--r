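Package: sbipredict
Title: Multi-Modal Prediction of Interaction Events Between Small-Molecule
    and Biotech Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts typed interaction events between small-molecule drugs
    (SMILES) and biotech drugs (amino-acid sequences) from multi-modal drug
    representations: tokenized sequences fed to 1D convolutional encoders,
    hashed path fingerprints and k-mer protein embeddings, and Jaccard
    similarity profiles over four heterogeneous interaction networks
    (drug-drug and drug-protein). Negative training pairs are selected from
    the unlabeled candidate space by a positive-unlabeled undersampling
    procedure built on repeated balanced decision-tree scoring. Includes a
    seeded synthetic drug-universe generator with planted signal, a
    cross-validation and metrics harness, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    jsonlite,
    yaml,
    ChemmineR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
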