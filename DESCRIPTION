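Package: polytopo
Title: Staged 3D-Genome Analysis for Allopolyploid Subgenomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of staged Hi-C and expression data in an
    allotetraploid genome with At and Dt subgenomes: ICE matrix balancing,
    distance-decay contact probability and compactness summaries, A/B
    compartment calling with four-stage trajectory classification,
    insulation-score TAD-like structure calling with cross-stage boundary
    conservation and inter-subgenome homoeologous/partitioned pairing,
    TAD-clique detection from loop-mediated inter-domain interactions via a
    size-normalised interaction-strength statistic, chromatin-loop calling
    and anchor taxonomies, homoeolog pairing through syntenic-block
    reciprocal best hits, homoeolog expression-bias calling, and
    homoeologous-gene interaction networks with divergence measures. A
    synthetic-data module generates a two-subgenome, four-stage dataset with
    planted structures at every level so each analysis stage has a
    recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
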