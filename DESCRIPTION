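Package: kmerattn
Title: Multi-Scale k-mer Attention Classification of circRNA, lncRNA and mRNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Three-class RNA sequence classification (circRNA vs. lncRNA vs.
    mRNA) from fused 3/4/5-mer composition features passed through a
    multi-head scaled dot-product attention network, together with the
    surrounding workflow: FASTA input and curation (exact deduplication,
    minimum-length filtering, greedy redundancy reduction at 80 percent
    identity, inter-group deduplication, stratified 70/15/15 splitting),
    classical nucleotide descriptor baselines (NAC, CKSNAP, DAC, DCC, DACC,
    PseKNC, PCPseDNC), macro- and support-weighted multi-class evaluation
    metrics, and sequence-variability analyses (GC content with
    Kruskal-Wallis testing, longest open reading frame, standardized
    2-D UMAP embedding with outlier detection). A seeded generator of
    three RNA-like sequence classes with controllable GC content, ORF
    structure and k-mer motif biases makes the whole pipeline testable
    without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    uwot,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
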