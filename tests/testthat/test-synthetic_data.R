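test_that("germline catalogue has the requested size and is deterministic", {
  cfg <- simulation_config(seed = 5, n_clones = 2, depth = 4,
                           n_v_segments = 5, n_j_segments = 3)
  cat1 <- generate_germline_set(cfg)
  cat2 <- generate_germline_set(cfg)
  expect_equal(nrow(cat1$v), 5)
  expect_equal(nrow(cat1$j), 3)
  expect_identical(cat1, cat2)
  cfg1 <- simulation_config(seed = 5, n_clones = 1, depth = 1,
                            n_v_segments = 1, n_j_segments = 1)
  cat_min <- generate_germline_set(cfg1)
  expect_equal(nrow(cat_min$v), 1)
  expect_equal(nrow(cat_min$j), 1)
})

test_that("any two generated V segments differ at >= 3 positions", {
  cfg <- simulation_config(seed = 9, n_clones = 2, depth = 4,
                           n_v_segments = 12, n_j_segments = 6)
  cat <- generate_germline_set(cfg)
  for (segs in list(cat$v$sequence, cat$j$sequence)) {
    for (a in seq_along(segs)) {
      for (b in seq_len(a - 1)) {
        expect_gte(hamming(segs[a], segs[b]), 3)
      }
    }
  }
  # anchors in place
  expect_true(all(endsWith(cat$v$sequence, "TGT")))
  expect_true(all(startsWith(cat$j$sequence, "TGG")))
})

test_that("naive rearrangement assembles V + insertion + J with in-frame junction", {
  cfg <- simulation_config(seed = 7, n_clones = 2, depth = 4)
  cat <- generate_germline_set(cfg)
  anc <- simulate_naive_rearrangement(cat, cfg, seed = 42)
  vseq <- cat$v$sequence[anc$v_idx]
  jseq <- cat$j$sequence[anc$j_idx]
  expect_true(startsWith(anc$sequence, vseq))
  expect_true(endsWith(anc$sequence, jseq))
  expect_equal(nchar(anc$junction) %% 3, 0)
  expect_equal(nchar(anc$junction_aa), nchar(anc$junction) / 3)
  # junction anchors: Cys at the start, Trp at the end
  expect_equal(substr(anc$junction_aa, 1, 1), "C")
  expect_equal(substr(anc$junction_aa, nchar(anc$junction_aa),
                      nchar(anc$junction_aa)), "W")
  # determinism
  anc2 <- simulate_naive_rearrangement(cat, cfg, seed = 42)
  expect_identical(anc, anc2)
  # zero insertion: junction is just the two anchor codons
  anc0 <- simulate_naive_rearrangement(cat, cfg, seed = 1,
                                       insertion_length = 0)
  expect_equal(nchar(anc0$junction), 6)
})

test_that("V usage covers the catalogue under repeated draws", {
  cfg <- simulation_config(seed = 3, n_clones = 2, depth = 4,
                           n_v_segments = 5, n_j_segments = 2)
  cat <- generate_germline_set(cfg)
  v_used <- vapply(1:1000, function(s) {
    simulate_naive_rearrangement(cat, cfg, seed = s)$v_idx
  }, numeric(1))
  expect_setequal(unique(v_used), 1:5)
})

test_that("tree topology is a valid rooted tree", {
  t1 <- sample_tree_topology(1, seed = 1)
  expect_equal(t1$n_nodes, 1)
  expect_true(is.na(t1$parent[1]))
  t5 <- sample_tree_topology(5, seed = 2)
  expect_equal(sum(!is.na(t5$parent)), 4)  # |E| = |V| - 1
  expect_true(all(t5$parent[-1] < 2:5))    # recursive: parents precede
  expect_error(sample_tree_topology(0, seed = 1), "n_nodes")
  # both labeled 3-node shapes (chain and star) occur under reseeding
  shapes <- vapply(1:50, function(s) {
    paste(sample_tree_topology(3, seed = s)$parent[-1], collapse = ",")
  }, character(1))
  expect_setequal(unique(shapes), c("1,1", "1,2"))
  # depth cap respected
  deep <- sample_tree_topology(50, seed = 4, max_depth = 2)
  expect_lte(max(deep$depth), 2)
})

test_that("zero mutation rate leaves every lineage node identical", {
  tree <- sample_tree_topology(6, seed = 3)
  seqs <- mutate_lineage("ACGTACGTACGTACGT", tree, targeting_model(),
                         rate = 0, seed = 1)
  expect_true(all(seqs == "ACGTACGTACGTACGT"))
})

test_that("per-edge mutation count matches the binomial expectation", {
  set.seed(99)
  anc <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  tree <- structure(list(n_nodes = 2, parent = c(NA, 1L), depth = c(0L, 1L)),
                    class = "lineage_tree")
  flat <- targeting_model(hotspot_fold = 1, coldspot_fold = 1)
  muts <- vapply(1:200, function(s) {
    seqs <- mutate_lineage(anc, tree, flat, rate = 0.01, seed = s)
    hamming(seqs[1], seqs[2])
  }, numeric(1))
  # mean ~ Binomial(300, 0.01) = 3; se of the mean over 200 reps ~ 0.12
  expect_gt(mean(muts), 2.4)
  expect_lt(mean(muts), 3.6)
})

test_that("hotspot contexts mutate at the configured rate ratio", {
  set.seed(7)
  anc <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
  chars <- strsplit(anc, "")[[1]]
  model <- targeting_model(hotspot_fold = 10, coldspot_fold = 1)
  tree <- structure(list(n_nodes = 2, parent = c(NA, 1L), depth = c(0L, 1L)),
                    class = "lineage_tree")
  # classify hotspot centers independently: WRC (W=A/T, R=A/G) and GYW
  is_hot <- vapply(seq_along(chars), function(i) {
    if (i < 3 || i > length(chars) - 2) return(FALSE)
    (chars[i] == "C" && chars[i - 1] %in% c("A", "G") &&
       chars[i - 2] %in% c("A", "T")) ||
      (chars[i] == "G" && chars[i + 1] %in% c("C", "T") &&
         chars[i + 2] %in% c("A", "T"))
  }, logical(1))
  hot_pos <- which(is_hot)
  hot <- cold <- 0
  n_hot <- length(hot_pos)
  n_cold <- nchar(anc) - n_hot
  for (s in 1:400) {
    seqs <- mutate_lineage(anc, tree, model, rate = 0.02, seed = s)
    diff <- which(strsplit(seqs[2], "")[[1]] != chars)
    hot <- hot + sum(diff %in% hot_pos)
    cold <- cold + sum(!diff %in% hot_pos)
  }
  rate_ratio <- (hot / n_hot) / (cold / n_cold)
  expect_gt(rate_ratio, 5)   # configured ratio 10, generous sampling band
  expect_lt(rate_ratio, 20)
})

test_that("simulated repertoires conserve ground truth and respect knobs", {
  sim <- random_sim(41, n_clones = 12, depth = 60)
  rec <- sim$repertoire$records
  expect_false(any(is.na(rec$clone_id_true)))
  expect_equal(length(unique(rec$clone_id_true)), 12)
  expect_equal(sum(clone_sizes(sim$truth)), n_records(sim$repertoire))
  # frame safety: junctions translate, anchors intact at rate 0
  sim0 <- random_sim(42, n_clones = 10, depth = 30, rate = 0)
  aa <- sim0$repertoire$records$junction_aa
  expect_true(all(startsWith(aa, "C") & endsWith(aa, "W")))
  # zero-mutation collapse: each clone is one distinct sequence
  expect_lte(length(unique(sim0$repertoire$records$sequence)), 10)
  # forced singletons
  sim1 <- simulate_repertoire(simulation_config(seed = 43, n_clones = 15,
                                                depth = 15,
                                                singleton_fraction = 1))
  expect_true(all(clone_sizes(sim1$truth) == 1))
})

test_that("identical configuration yields byte-identical AIRR output", {
  cfg <- simulation_config(seed = 77, n_clones = 8, depth = 40,
                           emit_light_chain = TRUE)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_rearrangements(simulate_repertoire(cfg)$repertoire, p1)
  write_rearrangements(simulate_repertoire(cfg)$repertoire, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("adding clones does not perturb earlier clones' draws", {
  base <- simulate_repertoire(simulation_config(seed = 55, n_clones = 5,
                                                depth = 25))
  more <- simulate_repertoire(simulation_config(seed = 55, n_clones = 8,
                                                depth = 25))
  a <- base$repertoire$records
  b <- more$repertoire$records
  # the ancestors (V/J choice, junction) of the first five clones are
  # untouched; only the depth allocation across clones may shift
  for (cl in sprintf("C%04d", 1:5)) {
    expect_identical(unique(a$v_call[a$clone_id_true == cl]),
                     unique(b$v_call[b$clone_id_true == cl]), info = cl)
    expect_identical(unique(a$j_call[a$clone_id_true == cl]),
                     unique(b$j_call[b$clone_id_true == cl]), info = cl)
    expect_identical(unique(nchar(a$junction[a$clone_id_true == cl])),
                     unique(nchar(b$junction[b$clone_id_true == cl])),
                     info = cl)
  }
})

test_that("configured mutation rate maps monotonically to realized load", {
  loads <- vapply(c(0, 0.01, 0.04), function(r) {
    mean(vapply(1:5, function(s) {
      mutation_load(random_sim(100 + s, n_clones = 8, depth = 60,
                               rate = r)$repertoire)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(loads) > 0))
  expect_equal(loads[1], 0)
})

test_that("light-chain emission is clone-consistent at zero discordance", {
  sim <- random_sim(61, n_clones = 8, depth = 40, emit_light_chain = TRUE)
  rec <- sim$repertoire$records
  expect_false(any(is.na(rec$lc_v_call)))
  pairs_per_clone <- tapply(paste(rec$lc_v_call, rec$lc_j_call),
                            rec$clone_id_true,
                            function(x) length(unique(x)))
  expect_true(all(pairs_per_clone == 1))
})

test_that("per-sample mixing allocates clone members across samples", {
  mix <- matrix(0, nrow = 6, ncol = 2)
  mix[1:2, ] <- 0.5          # clones 1-2 split across both samples
  mix[3:6, 1] <- 1           # rest pure sample 1
  sim <- simulate_repertoire(simulation_config(
    seed = 71, n_clones = 6, depth = 60, singleton_fraction = 0,
    n_samples = 2, per_sample_mixing = mix))
  rec <- sim$repertoire$records
  split_clones <- tapply(rec$sample_id, rec$clone_id_true,
                         function(x) length(unique(x)))
  expect_equal(as.integer(split_clones[sprintf("C%04d", 1:2)]), c(2L, 2L))
  expect_equal(as.integer(split_clones[sprintf("C%04d", 3:6)]), rep(1L, 4))
})
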