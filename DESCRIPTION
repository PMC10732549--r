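Package: driftr
Title: Proteome-Wide Compound-Target Identification by Chemical Similarity and Attention-Based Interaction Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based pipeline for mapping the protein target space of
    small molecules. Query compounds are matched against an annotated compound
    library by path-based 1024-bit 2D fingerprints (Tanimoto similarity) and by
    distance-binned 3D pharmacophore keys computed over seeded conformer
    ensembles; the annotated targets of the retrieved "bait" compounds are then
    ranked by an attention-based compound-protein interaction network that
    predicts binding affinity (pKd) from the compound graph and the protein
    sequence. A rotatable-bond fragmenter partitions compounds into rigid
    fragments, and the network's fragment-residue attention map ranks the
    fragments that drive predicted binding. Includes dataset compilation rules
    and retrieval metrics (recall, precision, F-score, ROC AUC, Pearson r), and
    a synthetic-data generator that plants similarity clusters and a bilinear
    affinity model so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    pROC,
    optparse
Config/testthat/edition: 3
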