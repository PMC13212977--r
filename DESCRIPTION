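Package: pcndrp
Title: Drug Response Prediction with Pathway Crosstalk Network Graph Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts cell-line drug response (natural-log IC50 in micromolar)
    from transcriptomes summarized as pathway activity scores. Cell lines are
    represented as directed pathway crosstalk network (PCN) graphs built from
    three relations (protein-protein-interaction separation scores, gene
    regulatory network separation scores, and pathway score correlations),
    drugs as featurized atom-bond graphs parsed from SMILES. A relational
    graph convolution encoder over the PCN and a multi-head graph attention
    encoder over atom graphs, both with dense cross-layer concatenation, feed
    a fully connected regression head; pathway attributions are obtained with
    Grad-CAM. Includes robust score scaling, response-table ingestion and
    deduplication, four blinding evaluation scenarios with cross-validated
    training and early stopping, a fully synthetic benchmark world, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    ChemmineR,
    ChemmineOB,
    e1071,
    yaml,
    stats,
    utils,
    methods,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
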