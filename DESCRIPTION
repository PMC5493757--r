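Package: vhlink
Title: Linking Active Viral Infections to Candidate Eukaryotic Hosts from
    Metatranscriptomic Marker-Gene Co-Occurrence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers putative virus-host relationships of single-celled
    eukaryotes from poly-A selected metatranscriptome marker-gene expression.
    Read counts are rarefied to a common library depth and length-normalized
    ("rarefied counts per kilobase", RCK), contig expression profiles are
    compared by Pearson correlation, clustered by group-average (UPGMA)
    agglomeration, and statistically distinct clusters are delimited by a
    recursive similarity-profile (SIMPROF) permutation test. Clusters that
    contain both viral (MCP, RdRP, Rep) and eukaryotic (RPB1) marker contigs
    are extracted into significance-filtered correlation networks, and viral
    temporal dynamics are classified as steady-state versus boom-and-bust.
    Includes a seeded synthetic-community generator with planted virus-host
    pairs for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    igraph,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
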