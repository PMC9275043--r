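Package: seagea
Title: Seascape Genomics: Genotype-Environment Association by Partial
    Redundancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects loci putatively under selection in marine
    populations by relating a SNP genotype matrix to environmental
    gradients while controlling for spatial structure. Provides a
    synthetic seascape generator with a planted truth set, genotype
    quality control (minor-allele-count and relatedness filters),
    least-cost oceanic distances and distance-based Moran's eigenvector
    maps, environmental-variable reduction (correlation, variance
    inflation, forward selection), partial redundancy analysis with
    permutation tests and outlier-locus detection, population structure
    summaries (heterozygosity, Weir-Cockerham F_ST, PCA, EM mixture
    clustering with AIC/cross-validation model choice), and Gene
    Ontology enrichment of candidate loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    igraph,
    geosphere,
    jsonlite,
    yaml,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
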