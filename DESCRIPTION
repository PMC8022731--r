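Package: nigontools
Title: Ancestral Linkage Group (Nigon Element) Inference and Telomere-End
    Analysis for Nematode Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers ancestral nematode linkage groups (Nigon elements) from
    chromosome-level genome assemblies by collating single-copy ortholog
    locations into an ortholog-by-species chromosomal allocation matrix,
    computing Dice colocation similarity, clustering with partitioning around
    medoids (PAM) or its subsampling variant CLARA, selecting the number of
    clusters by average silhouette width, and assigning loci to labeled
    elements under taxon-agreement and cluster-size thresholds. Provides
    window-based chromosome painting, reciprocal-best-hit projection of
    element labels onto further genomes, gene-neighborhood divergence
    statistics, and feature-density tracks. Includes a telomere toolkit that
    scans assemblies for tandem telomere repeats, detects dual telomere-repeat
    addition sites from soft-clipped long-read alignments, quantifies
    short/long chromosome-form mixtures, and performs subtelomeric extension,
    assembly-gap and collapsed-repeat copy-number arithmetic. A synthetic
    karyotype-evolution and read generator provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
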