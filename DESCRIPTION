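Package: clustx
Title: Translated Protein Homology Search with a Clustered Seed Index
Version: 0.1.0
Authors@R: person("clustx", "developers", role = c("aut", "cre"),
    email = "clustx@example.org")
Description: A BLASTX-like translated search of short DNA reads against a
    protein database, accelerated algorithmically rather than by hardware:
    fixed-length database subsequences are clustered in a reduced amino-acid
    alphabet, and a triangle-inequality lower bound on the cluster
    member-representative distances prunes seed candidates before any full
    distance is computed.  Seeds are extended with X-dropoff ungapped and
    affine-gap gapped extension, thinned by chain filtering, and reported
    with Karlin-Altschul E-values in BLAST tabular format.  Includes a
    deterministic two-phase batched scheduler over database chunks, a
    seeded metagenomic read simulator, and a full Smith-Waterman reference
    implementation for oracle testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
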