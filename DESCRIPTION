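Package: moable
Title: Coembedding of Compound Structures and Perturbation Signatures for
    Mechanism-of-Action Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains a two-encoder metric-learning model that maps compound
    chemical fingerprints (ECFP) and compound-induced transcriptomic
    signatures (L1000-style landmark-gene profiles) into a shared embedding
    space with a cosine-similarity triplet loss.  Mechanisms of action are
    predicted by scoring embedding connectivity between a compound and
    genetic-perturbation (knock-down, knock-out, over-expression) signature
    embeddings, ranking perturbed genes by the maximum cosine similarity per
    gene, and running preranked gene set enrichment analysis with a
    permutation null over that ranking.  Includes GCT/GMT/TSV readers and
    writers, compound-disjoint dataset splitting, raw-signature baseline
    modes, evaluation protocols (true-pathway p-value distributions and
    FDR-threshold AUROC), Tanimoto stratification of unseen compounds, and a
    self-contained synthetic corpus generator with a planted
    compound-target-pathway linkage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    fgsea
Config/testthat/edition: 3
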