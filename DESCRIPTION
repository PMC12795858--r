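Package: tfbranch
Title: Branches of Binding-Site Motif Similarity in the Transcription
    Factor DBD Hierarchy
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links the DNA-binding-domain (DBD) structural hierarchy of
    transcription factors (superclass, class, family, subfamily, TF) to
    the similarity of their binding-site motifs.  Provides readers for
    JASPAR PFM, MEME minimal and Hocomoco PCM motif dialects, a
    TomTom-style motif-pair comparison score (-log10 p-value of the best
    gapless alignment under per-column Pearson correlation, with either a
    permutation or an exact convolution null), TF-pair and TF-set
    similarity metrics (Min/Q1/Q2/Q3/Max over the motif- and TF-pair
    score distributions), a greedy branch-finding algorithm that
    partitions each class into maximal sets of sister units whose median
    TF-pair similarity exceeds a threshold, UPGMA-scheme similarity trees
    with Newick export, and a seeded generator of synthetic motif
    collections with planted branch structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
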