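Package: peptigraph
Title: Fragment-Based Heterogeneous Graph Representation Learning for
    Canonical and Non-Canonical Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds molecular graphs of peptides containing canonical and
    non-canonical amino acids, fragments them with an amide-preserving
    domain-knowledge operator (Amiibo) and a data-driven BRICS-based
    vocabulary operator (AdaFrag), assembles atom/fragment/junction
    heterogeneous graphs, pre-trains a message-passing encoder by
    masked-attribute prediction under four masking strategies and a
    two-stage (canonical then non-canonical) schedule, and fine-tunes
    pooled multi-view embeddings for peptide property prediction.
    Includes a synthetic peptide corpus generator with planted fragment
    motifs and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    nnet,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
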