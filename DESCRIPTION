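Package: folddict
Title: Lossless Dictionary Compression of Protein Folding Pattern Tableaux
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Represents protein folding patterns as tableaux (the order of
    helices and strands along the chain, their pairwise contacts, and the
    interaxial dihedral angles of contacting pairs), infers a dictionary of
    recurrent substructural concepts by minimum message length (MML) lossless
    compression with simulated annealing, optimally dissects any tableau
    against a dictionary by dynamic programming, and relates concepts
    hierarchically through meta-concept feature vectors clustered by cosine
    similarity and UPGMA. Includes a von Mises angle codec with a working
    arithmetic encoder/decoder proving losslessness, a synthetic tableau
    generator with planted motifs for benchmarking, and command-line style
    entry points for building tableaux from PDB/mmCIF coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
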