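Package: cnnloh
Title: Six-State Integration of LOH and Copy Number in Tumor Trios with
    Expression
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genome-wide integration of loss-of-heterozygosity (LOH) and
    copy-number (CN) state from paired tumor/adjacent-normal/blood SNP-array
    trios. Calls per-SNP LOH against the matched blood reference, assigns
    five-level CN states from sliding-window smoothed intensity log ratios,
    combines them into a six-state LOH-by-CN classification with contiguous
    segments over informative SNPs, tabulates per-case and per-arm LOH
    burden by CN group, and relates copy-number-neutral LOH (CNNLOH) to
    gene expression via unpaired t-tests on tumor/normal log2 fold changes.
    Includes a synthetic trio-cohort simulator with planted six-state
    events for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: CopyNumberVariation, SNP, GeneExpression, Software
RoxygenNote: 7.3.3
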