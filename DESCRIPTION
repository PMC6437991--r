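Package: ontolink
Title: Unsupervised Biomedical Entity Normalization with Word Embeddings
    and Syntactic Re-Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links biomedical entity mentions in text to concepts of an
    ontology (OBO format) or a flat dictionary (TSV) without labeled
    training data. Mentions and concept terms are embedded by averaging
    pre-trained word vectors; candidate concepts are ranked by cosine
    similarity (or word mover's distance) and the top candidates are
    re-ranked by a convex combination of the phrase similarity and the
    similarity of the constituency-parse head words. Includes readers and
    writers for OBO ontologies, word2vec vector files, BioNLP-ST standoff
    annotation (.a1/.a2) and generic mention/gold TSV formats, an
    ontology-aware evaluation based on Wang semantic similarity as well as
    exact-match micro/macro precision/recall/F-score, two reference
    baselines, and a deterministic synthetic-fixture generator so the full
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
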