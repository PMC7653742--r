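Package: pavpan
Title: Gene Presence-Absence Variation and Pan-Genome Analysis from Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene presence-absence variation (PAV) from whole-genome
    resequencing depth tracks. Computes per-gene mean exonic coverage from
    bedGraph depth profiles and GFF3/BED12 annotations, calibrates each
    individual's hemizygous and homozygous depth peaks from the bimodal
    coverage distribution, classifies genes as absent, hemizygous or
    homozygous, partitions the gene complement into core and dispensable
    sets, quantifies pan-genome openness with a power-law fit to gene
    accumulation curves, tests Mendelian segregation of dispensable genes
    in crosses, models the impact of allelic divergence and mapping
    stringency on observed coverage, and performs hypergeometric term
    enrichment of the dispensable gene set. Includes a synthetic diploid
    pan-genome and depth-track simulator so the whole pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
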