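Package: rtchimera
Title: Transcriptional Readthrough and mRNA Chimera Analysis from
    Stranded RNA-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects transcriptional readthrough loci from strand-specific
    RNA-seq coverage by comparing normalized read density in fixed-length
    windows downstream of annotated genes between a mutant and a wild-type
    library, and characterizes the resulting gene1/gene2 chimera-forming
    pairs: hypergeometric overlap statistics between candidate sets across
    genotypes, cross-genome adjacency (microsynteny) classification of gene
    pairs from homolog hit tables, chromatin-state assignment and
    Monte-Carlo chi-square distribution tests, Nei-Gojobori (1986) Ka/Ks
    estimation for codon-aligned pairs, and polyA-site mapping of 3' RACE
    clone ends.  A seeded synthetic-data generator produces annotations,
    stranded coverage with planted readthrough, homolog-hit tables,
    chromatin-state assignments and codon pairs evolved at a known dN/dS,
    together with machine-readable truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
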