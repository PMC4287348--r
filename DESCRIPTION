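Package: siphonatlas
Title: Intracellular Transcriptomic Atlas Pipeline for Siphonous Algae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds pseudo-organ expression atlases for coenocytic
    (siphonous) macroalgae from transcript-level RNA-seq counts:
    low-count filtering, trimmed-mean-of-M-values normalization,
    pairwise negative-binomial differential-abundance tests with
    Benjamini-Hochberg FDR control, self-organizing-map partitioning of
    scaled accumulation profiles on a hexagonal grid, a resampling plus
    linear-discriminant-analysis procedure for choosing the cluster
    number, per-cluster GO term over-representation with optional
    transcript-length bias correction, and a chi-squared statistic
    linking clusters to a second species' expression atlas through
    best-BLAST-hit homology.  A synthetic-data generator with planted
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    edgeR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
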