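Package: magcat
Title: Genome Catalog Construction and Cross-Host Microbiome Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds dereplicated species catalogs from metagenome-assembled
    genomes (MAGs) and isolate assemblies, and compares two catalogs across
    hosts. Genomes are quality-filtered on a checkM-derived quality score
    (completeness minus five times contamination) and assembly contiguity
    (N50), pairwise average nucleotide identity (ANI) is estimated with
    bottom-s MinHash sketches of canonical k-mers, species are delineated at
    95 percent ANI by average-linkage hierarchical clustering after graph
    pre-clustering at 80 percent ANI, and one representative per species is
    chosen by a score that prefers isolates over MAGs. Downstream tools parse
    GTDB-style lineages with deterministic placeholder naming, quantify taxon
    overlap between catalogs at every rank, and analyse compositional
    abundance tables with the centered log-ratio transform (multiplicative
    zero replacement), Pearson correlation of mean abundances, KEGG-module
    presence scoring, and Welch tests with Benjamini-Hochberg correction.
    A synthetic-data module simulates strain genomes at controlled ANI,
    fragmented assemblies at a target N50, and multinomial count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
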