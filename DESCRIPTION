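Package: neurodict
Title: Neural Dictionary Models for Ontology Concept Recognition in Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains a neural dictionary that ranks biomedical ontology
    concepts (for example Human Phenotype Ontology or SNOMED-CT terms)
    matching a free-text phrase. Phrases are encoded with a width-one
    convolutional layer, max-over-time pooling and a dense projection;
    concept embeddings are composed along the ontology taxonomy through a
    sparse ancestry matrix so that each concept learns only its position
    relative to its parents. Includes an n-gram document annotator with
    overlap resolution, negative sampling against a dummy NONE class,
    micro/macro/ancestor-extended evaluation metrics with threshold
    selection, an OBO parser with ancestor-closed subset extraction, a
    word2vec-format word-vector loader, and deterministic synthetic
    fixtures (toy ontologies, word vectors and annotated corpora) for
    testing the full pipeline offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
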