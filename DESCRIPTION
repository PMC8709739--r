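Package: comirnet
Title: Weighted Co-Expression Modules and miRNA-mRNA Network Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers co-expression modules from paired mRNA and miRNA
    expression profiles using weighted correlation network analysis:
    z-score normalization and FDR-controlled differential-expression
    filtering, soft-thresholded unsigned adjacency with scale-free
    topology power selection, topological-overlap (TOM) dissimilarity,
    average-linkage module detection with color-coded labels, module
    eigengenes and module-trait statistics (gene significance, module
    membership, module significance), intramodular hub calling, and
    integration of hub miRNAs with gene-module members through a
    multi-source scored interaction table ranked and cut to a bipartite
    regulatory network annotated with degree and normalized betweenness
    centrality. Includes a seeded synthetic-data generator with planted
    modules, traits, and regulators so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
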