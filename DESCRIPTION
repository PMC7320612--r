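Package: mxscaff
Title: Minimizer-Graph Assembly-Guided Scaffolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Contiguates and optionally corrects a draft (target) genome
    assembly using one or more reference assemblies, without alignments.
    Ordered minimizer sketches of every input assembly are joined into a
    single weighted undirected graph whose nodes are strand-neutral minimizer
    hashes and whose edges record sketch adjacency; weight-based filtering
    reduces the graph to linear paths which are translated into ordered,
    oriented contig paths with reference-estimated gap sizes. Putative
    chimeric contigs can be cut at the inferred breakpoint. Outputs are
    scaffolded FASTA, an AGP v2.1 file, a path file and a Graphviz dot export
    of the minimizer graph. Includes a deterministic synthetic fixture
    generator with recorded ground truth and scoring utilities (junction and
    orientation accuracy, chimera-cut sensitivity, gap error, NG50).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
SystemRequirements: C++11
Config/testthat/edition: 3
RoxygenNote: 7.3.3
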