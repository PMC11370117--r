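# clonefam

Benchmarking B-cell clonal family inference on simulated repertoires
with known ground truth.

## The problem

A clonal family (CF) is the set of all B-cell receptor (BCR) sequences
descending from one unmutated common ancestor — a single VDJ
rearrangement diversified by somatic hypermutation. AIRR-seq data show
only the mutated sequences; grouping them back into families is an
inference step, and the field uses many incompatible conventions for it.
Because every repertoire summary (clone counts, diversity, dominance,
clone sharing) is computed *per family*, the convention chosen changes
the biology reported.

`clonefam` is for immunoinformaticians who want to quantify that effect.
It provides:

* a **repertoire simulator** with known clonal structure: synthetic
  germline V/J segments, VDJ recombination with in-frame junctional
  insertions, random lineage trees, and 5-mer context-dependent somatic
  hypermutation (WRC/GYW hotspots, SYC/GRS coldspots, or a targeting
  table loaded from TSV);
* the standard **inference approaches**: identical junction amino acids
  (A1), subclones (A2), fixed absolute/relative Hamming thresholds
  within V/J/junction-length groups with single-linkage components
  (A3–A5), a sample-specific threshold from the valley of the bimodal
  distance-to-nearest distribution (A6), and alignment-free tf-idf
  k-mer cosine clustering with a negation-calibrated threshold (A10);
* **edge-based scoring**: each family is the clique of its member pairs;
  over all C(n,2) pairs, TP/FP/FN/TN yield sensitivity TP/(TP+FN),
  precision TP/(TP+FP), F1 2TP/(2TP+FP+FN) and Jaccard TP/(TP+FN+FP);
* **outcome measures**: CF counts, singletons, dominant clones
  (frequency > 0.5%), D50, Hill diversity (Σ fᵢ^α)^(1/(1−α)) with its
  Shannon (−Σ fᵢ ln fᵢ) and Gini-Simpson (1 − Σ fᵢ²) specializations,
  and mutation load;
* **downstream analyses**: shared clonal families across merged samples
  and heavy/light-chain concordance;
* a **benchmark driver** that runs simulate → infer → evaluate over
  replicates and writes a deterministic tidy summary.

AIRR Rearrangement TSV is read and written throughout, so real
annotated repertoires can be scored with the same machinery.

## Worked example

```r
library(clonefam)

sim <- simulate_repertoire(simulation_config(seed = 1, n_clones = 50,
                                             depth = 400))
tab <- evaluate_approaches(sim$repertoire, c("A1", "A2", "A4", "A5", "A6"))
tab[, c("approach", "sensitivity", "precision", "f1", "jaccard",
        "n_cf", "n_singletons")]
#>   approach sensitivity precision    f1 jaccard n_cf n_singletons
#> 1       A1       0.742         1 0.852   0.742   80           32
#> 2       A2       0.742         1 0.852   0.742   80           32
#> 3       A4       0.993         1 0.997   0.993   51           21
#> 4       A5       1.000         1 1.000   1.000   50           21
#> 5       A6       0.974         1 0.987   0.974   54           23

summarize_outcomes(sim$truth, sim$repertoire)
#>   approach n_cf n_singletons mean_size max_size n_dominant d50 shannon
#> 1     TRUE   50           21         8       45         29   9   3.384
#>   gini_simpson mutation_load
#> 1        0.954        0.9193
```

Reading the numbers: the simulation planted 50 families (21 of them
singletons) in 400 records at a realized mutation load of ~0.9%. The
threshold-based approaches (A4–A6) recover the planted structure almost
perfectly, while the exact-match references A1/A2 fragment mutated
families into 80 clusters — their sensitivity of 0.74 means a quarter of
the true within-family pairs are lost, which is why identical-junction
clustering is a poor surrogate for clonal families on mutated
repertoires. Precision 1 throughout reflects the collision-free design:
no two planted families share a V/J/junction-length group, so no
approach can merge them.

The full loop over replicates:

```r
cfg <- benchmark_config(simulation = simulation_config(n_clones = 50,
                                                       depth = 400),
                        approaches = c("A2", "A4", "A6"),
                        replicates = 3, base_seed = 1,
                        output_dir = "bench_out")
res <- run_benchmark(cfg)   # writes AIRR TSVs, clone TSVs, eval JSONs,
head(res$summary)           # and a deterministic tidy summary.tsv
```

See `vignettes/clonefam-methods.Rmd` for the generative model, the
threshold-fitting details, and every numerical convention.

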