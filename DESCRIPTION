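Package: allopolyphase
Title: Subgenome Phasing, Genetic-Map Assembly Checking and Introgression
    Statistics for Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating subgenome-resolved assemblies of
    allotetraploid genomes. Implements F2 genetic-map based misassembly
    detection (marker state calling, 1:2:1 segregation filtering, false
    recombination counting, contig coding and linkage grouping), windowed
    parental-coverage subgenome assignment with homeologous-exchange
    breakpoint detection, homeolog pairing with interval-constrained rescue
    and systematic gene naming, reference-plus-SNP pseudoalignment
    construction, Patterson's D and f4-ratio introgression statistics with
    block jackknife, and Hi-C contact-matrix junction scoring including a
    simulated-translocation control. A synthetic allotetraploid generator
    with full ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
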