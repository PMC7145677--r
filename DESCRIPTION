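Package: enhcons
Title: Consensus Enhancer Calling from Multi-Assay Peak Evidence
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates peak calls from multiple epigenomic assay classes
    (P300/POLR2A ChIP-seq, histone marks, TF binding, DNase/ATAC, FAIRE,
    MNase, GRO-seq, CAGE, MPRA, STARR-seq, ChIA-PET) into a single weighted
    consensus enhancer track for one tissue or cell type. Datasets are
    filtered (peak-length cap, promoter/exon/insulator exclusion, coverage
    gates), signal-normalized to a length-weighted mean of one, merged
    within each evidence track by average-summit/average-width clustering,
    and combined across tracks with region-count Jaccard similarity weights
    and a 50 percent support rule. Includes a synthetic multi-track data
    generator with known ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
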