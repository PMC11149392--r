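Package: orthoclique
Title: Genetic Distances from Assembled RNA-Seq Transcriptomes via
    Reciprocal-Best-Match Clique Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes pairwise genetic distances between individuals from
    assembled RNA-seq transcriptomes. Orthologous genes are identified by
    reciprocal BLASTn best matches; a multipartite gene-matches graph is
    built over all samples and only genes lying in "ideal" components
    (cliques with exactly one gene per sample) contribute to the distance,
    which is one minus the ratio of identical bases to aligned bases summed
    over the retained ortholog alignments. Includes a desk-scale built-in
    aligner, a k-mer Jaccard baseline, a birth-death + HKY85 transcriptome
    simulator with known ground-truth phylogeny, neighbor-joining and
    principal coordinates analysis, parameter sweeps over gene and sample
    counts, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
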