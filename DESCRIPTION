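Package: clonefam
Title: Benchmarking B-Cell Clonal Family Inference on Simulated Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark B-cell receptor (BCR) clonal family (CF)
    inference. Simulates annotated heavy-chain repertoires with known clonal
    ground truth (VDJ recombination, lineage trees, 5-mer context-dependent
    somatic hypermutation), infers clonal families with junction-based
    Hamming-distance clustering (exact match, fixed absolute/relative
    thresholds, sample-specific distance-to-nearest thresholds) and an
    alignment-free tf-idf k-mer approach, scores inferred partitions against
    the truth with edge-based confusion measures (sensitivity, precision, F1,
    Jaccard), and computes repertoire outcome measures (clonal family counts,
    singletons, dominant clones, D50, Hill, Shannon and Gini-Simpson
    diversity, mutation load) together with downstream shared-clone and
    heavy/light-chain concordance analyses. Reads and writes AIRR
    Rearrangement TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
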