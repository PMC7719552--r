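Package: poeseq
Title: Parent-of-Origin Allele-Specific Expression Inference for
    Reciprocal Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects parent-of-origin gene expression from reciprocal
    crosses of haplodiploid insects. Starting from parental variant calls
    and offspring RNA-seq allelic read counts, the pipeline filters
    variants to parent-unique informative SNPs, builds maternal and
    paternal alternate reference genomes, assigns reads by exact
    (zero-mismatch) matching, and fits a per-gene quasibinomial logistic
    regression of maternal versus paternal counts with cross direction,
    family and reproductive status as factors. Genes are classified as
    maternally expressed, paternally expressed, lineage (subspecies)
    biased or biallelic using Benjamini-Hochberg corrected p-values and a
    conservatively averaged maternal expression proportion. Includes a
    synthetic-data generator with known truth, a simplified negative
    binomial differential expression stage, and downstream hypergeometric
    enrichment, overlap and chi-squared set statistics with
    reciprocal-best-hit ortholog mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
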