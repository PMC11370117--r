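---
title: "Benchmarking clonal family inference: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking clonal family inference: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonefam)
```

## The problem

A B-cell clonal family (CF) is the set of all B-cell receptor (BCR)
sequences descending from one unmutated common ancestor — a single VDJ
rearrangement diversified by somatic hypermutation (SHM). AIRR-seq
experiments observe the mutated sequences only; which sequences belong to
the same family must be inferred. Many inference conventions coexist in
the literature, from "identical junction amino acids" to alignment-free
k-mer clustering, and the choice changes every downstream summary of a
repertoire: clone counts, diversity, dominance, clone sharing between
samples.

`clonefam` makes that dependence measurable. It simulates repertoires in
which the family structure is known by construction, runs a panel of
inference approaches on them, and scores each approach against the ground
truth with an edge-based confusion framework.

## The inference approaches

All junction-based approaches operate on the *junction*: the CDR3
nucleotide region plus its two anchor codons (Cys104, Phe/Trp118), the
most variable part of the heavy chain.

| id  | grouping | sequence | rule |
|-----|----------|----------|------|
| A1  | none | junction AA | identical strings |
| A2  | V gene, J gene | junction AA | identical strings ("subclones") |
| A3  | V, J, junction length | junction AA | Hamming distance ≤ 1 |
| A4  | V, J, junction length | junction AA | normalized Hamming ≤ 0.15 |
| A5  | V, J, junction length | junction NT | normalized Hamming ≤ 0.15 |
| A6  | V, J, junction length | junction NT | sample-fitted threshold |
| A10 | none | full sequence | tf-idf k-mer cosine, negation threshold |

For A3–A6 the package builds, within each VJ/junction-length group, the
fully connected graph of sequences, removes edges above the threshold and
takes connected components. The component step is single linkage: a chain
of near neighbours joins one family. The edge criterion is `distance <=
threshold`, so A3's "at most one amino acid" links pairs differing at
exactly one position.

**A6 (sample-specific threshold).** Each record's normalized Hamming
distance to its nearest *non-identical* neighbour within its VJ group is
collected; duplicates are excluded because identical reads would put a
spurious spike at zero. A Gaussian kernel density with Silverman's
rule-of-thumb bandwidth is evaluated on a 512-point grid over [0, 1]. If
the density has two or more local maxima, the threshold is the density
minimum between the two highest maxima — the valley separating
within-family from between-family distances. If not (degenerate or
unimodal distributions), the documented fallback of 0.15 is used and the
fit is flagged `bimodal = FALSE`.

**A10 (alignment-free).** Full sequences are embedded as tf–idf weighted
k-mer vectors (`tf` = raw k-mer count in the sequence, `idf = ln(N/df)`
over the joint corpus of repertoire and negation sequences; k defaults
to 4, the source method's k not being restated in the benchmark we
mirror). The clonal threshold is calibrated by *negation*: cosine
distances from each repertoire sequence to its nearest sequence from a
different individual are computed, and the threshold is set to the 0.10
quantile of those distances ("10% of the distances to negation
sequences", which we read as a quantile). Clustering is again connected
components. A10 requires a genuinely different individual; the benchmark
supplies one by simulating a second repertoire with independent clones
but the *same* germline catalogue — with disjoint germlines the negation
distances would be biologically meaningless.

## The generative model

`simulate_repertoire()` composes five stages, mirroring how such
benchmarks construct ground truth, but fully parametric so no external
data are needed:

1. **Germline catalogue** — `n_v_segments` V and `n_j_segments` J
   nucleotide segments; every V ends with the Cys anchor codon, every J
   starts with the Trp anchor. Any two same-type segments differ at ≥ 3
   positions so gene-level VJ partitioning is well defined.
2. **Naive rearrangements** — per clone, a V and J draw plus a junctional
   insertion (Poisson length, padded to a multiple of 3 and kept
   stop-codon free, so every naive junction translates cleanly with its
   anchors). Clone ancestors occupy distinct (V, J, junction-length)
   triples unless `collision_rate > 0`, making the difficulty of the
   inference problem controllable and perfect-recovery checks possible.
3. **Clone sizes** — heavy-tailed weights (power law by default) scaled
   to the target `depth`; a configurable fraction of clones is forced to
   singleton status.
4. **Lineage trees** — random recursive topologies (node *i* attaches
   uniformly to an earlier node, depth-capped), each node a subclone with
   a geometric copy-number weight.
5. **SHM** — along every tree edge, each site mutates with probability
   `rate ×` the 5-mer mutability of its context, normalized to mean 1.
   Substitution only, so junction coordinates never move. The default
   targeting model is flat with WRC/GYW hotspots at 5× and SYC/GRS
   coldspots at 0.3× — a configurable stand-in for published human 5-mer
   targeting tables, which `load_targeting_model()` can read from TSV.

All randomness flows from one seed through named streams (per clone, per
edge), so enlarging `n_clones` leaves earlier clones' ancestors
untouched, and identical configurations give byte-identical AIRR output.

### Default study conditions

The defaults are one fixed choice of realistic conditions, not tuning
knobs: 200 clones at depth 1000 (a mid-depth bulk sample), power-law
clone sizes with exponent 2.5 and 40% singletons (repertoires are
singleton-heavy), 20 V / 6 J segments of 150/42 nt (a scaled-down gene
set that keeps VJ groups populated), Poisson(36) insertions giving
junctions of ≈ 14 amino acids, and a per-edge mutation rate of 0.005
(≈ 0.5–1% realized V/J mutation load, at the low end of experimental
samples; the acceptance script also sweeps 0, 0.005, 0.02).

### What the generator does not emulate

No indels during SHM (length-discordant reads are discarded in the
practice we mirror), no D-segment or allele polymorphism modelling, no
sequencing error distinct from SHM, no selection or affinity maturation
dynamics, and germline segments are random rather than IMGT sequences.
Consequently, passing benchmarks here demonstrate correctness of the
inference machinery and its relative behaviour under mutation load and
depth — not absolute performance on experimental data, where annotation
errors and allele ambiguity add failure modes the simulation excludes.

## Scoring: edge-based confusion

Each family — true or inferred — is expanded to the clique of its member
pairs. Over the universe of all `C(n,2)` unordered pairs: TP are pairs
co-clustered in both partitions, FP only in the inference, FN only in
the truth, TN the rest (computed algebraically from the pair total; an
exhaustive enumerator is kept as a test oracle). Because TN dominates,
accuracy and specificity are reported but not discriminative; the
informative measures are sensitivity `TP/(TP+FN)`, precision
`TP/(TP+FP)`, F1 `2TP/(2TP+FP+FN)` and Jaccard `TP/(TP+FN+FP)`.
Undefined ratios (0/0) surface as `NA`, never silently as 0 or 1.

## Outcome measures

From a partition's clone-size distribution `f`: number of CFs,
singletons, mean/max size, dominant clones (frequency strictly above
0.5%), D50 (smallest number of clones covering ≥ 50% of records, ties
broken by label order), Hill diversity `(Σ f_i^α)^(1/(1−α))`, Shannon
index `−Σ f_i ln f_i` (the α→1 Hill limit; natural log to match the
defining formula, log2 behind a flag) and Gini–Simpson `1 − Σ f_i²`,
which equals `1 − 1/²D` exactly. Frequencies count records (reads), with
a distinct-sequence mode behind a flag. Mutation load is the mean of
`100·(v_mut + j_mut)/(v_len + j_len)` over records — junction mutations
excluded by construction.

## Downstream analyses

**Shared clones.** Samples are merged keeping per-record sample labels;
a family is shared when its members span ≥ 2 samples. Similarity
thresholds are *not* loosened for shared-family detection. Dominance of
shared families is assessed on merged frequencies; the shared fraction
uses the merged family total as denominator.

**Light-chain concordance.** A heavy-chain family is concordant when all
members pair to one light-chain V/J gene pair (gene level); singletons
are trivially concordant. Families containing a record without
light-chain calls are excluded from the denominator and counted
separately — conservative, and reported rather than hidden.

## Numerical and degenerate-input conventions

* Multi-assigned V/J calls resolve to the first listed call, allele
  stripped — deterministic on a single record.
* Records whose junction length is not a multiple of 3 stay in NT-based
  approaches and are excluded from AA-based ones (translation
  undefined).
* `fit_sample_threshold()` errors when no VJ group has two records
  (advising a fixed threshold); all-identical groups yield the fallback.
* Zero-norm tf–idf vectors (sequences whose every k-mer occurs in every
  sequence) are treated as orthogonal to everything.
* Clone labels are opaque; every measure is invariant under relabeling
  and record reordering, and tests enforce this.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_repertoire(simulation_config(seed = 1, n_clones = 50,
                                             depth = 400))
tab <- evaluate_approaches(sim$repertoire, c("A1", "A2", "A4", "A5"))
tab[, c("approach", "sensitivity", "precision", "f1", "n_cf")]

cfg <- benchmark_config(simulation = simulation_config(n_clones = 50,
                                                       depth = 400),
                        approaches = c("A2", "A4", "A6"),
                        replicates = 3, base_seed = 1,
                        output_dir = "bench_out")
res <- run_benchmark(cfg)
head(res$summary)
```

The benchmark writes, per replicate, the simulated AIRR TSV, one clone
TSV and JSON parameter sidecar per approach, an evaluation JSON, and a
tidy `summary.tsv` (replicate × approach × measure) whose reruns under an
identical configuration are byte-identical; wall-clock and versions go to
a separate machine-readable run log so they cannot break determinism.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run at deliberately compact
scales — repertoires of 50–2000 records, 10–200 clones, 5–20 replicate
seeds — chosen so the full benchmark loop, including the brute-force
oracles, completes in minutes while the statistical checks (hotspot rate
ratios, threshold valleys, degradation monotonicity) retain comfortable
sampling margins.
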