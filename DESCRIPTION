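Package: memoryseq
Title: Drought Stress Memory Analysis from Expression and Methylome Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies gene expression trajectories across repeated
    drought/re-watering cycles into unit-change profiles and stress-memory
    categories, screens differentially expressed genes with an exact
    conditional count test, calls differentially methylated regions from
    per-cytosine bisulfite counts by a sliding-window Fisher procedure with
    Benjamini-Hochberg correction, and links methylation to memory-gene
    expression by Pearson correlation. Ships a seeded synthetic-data
    generator with planted ground truth so every stage is testable without
    external sequencing data, plus physiological indices (relative water
    content, Fv/Fm) used to monitor drought severity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
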