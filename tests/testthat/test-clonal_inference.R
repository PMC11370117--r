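test_that("hamming and normalized_hamming follow their definitions", {
  expect_equal(hamming("ACGT", "ACGT"), 0)
  expect_equal(hamming("ACGT", "ACGA"), 1)
  expect_equal(hamming("CARDYW", "CARNNW"), 2)
  expect_error(hamming("ACG", "ACGT"), "equal-length")
  expect_equal(normalized_hamming("ACGT", "ACGA"), 0.25)
  expect_equal(normalized_hamming("AAAA", "AAAA"), 0)
  expect_equal(normalized_hamming("AAAA", "TTTT"), 1)
  expect_error(normalized_hamming("", ""), "zero-length")
})

test_that("VJ partitioning groups by stripped genes and junction length", {
  rep <- make_rep(junction = c("TGTGCGAAATGGGCGTGG", "TGTGCGAAATGGGCGTGG",
                               "TGTGCGAAATGGGCGTGGTGG", "TGTGCGAAATGGGCGTGG"),
                  junction_aa = c("CAKWAW", "CAKWAW", "CAKWAWW", "CAKWAW"),
                  v_call = c("IGHV1-69*01", "IGHV1-69*02", "IGHV1-69*01",
                             "IGHV2-5*01"),
                  j_call = "IGHJ4*02")
  groups <- partition_by_vj(rep, "NT")
  expect_length(groups, 3)
  # allele variants of the same gene share a key
  key_18 <- groups[["IGHV1-69|IGHJ4|18"]]
  expect_equal(sort(rep$records$sequence_id[key_18]), c("s001", "s002"))
  # same V/J, different junction length: different keys
  expect_true("IGHV1-69|IGHJ4|21" %in% names(groups))
  # different V gene: different key
  expect_true("IGHV2-5|IGHJ4|18" %in% names(groups))
})

test_that("threshold clustering equals the brute-force transitive closure", {
  # worked toy examples
  expect_equal(partitions_equal(
    cluster_by_threshold(c("CARDYW", "CARDFW", "CARNNW"), 1),
    c(1, 1, 2)), TRUE)
  expect_equal(partitions_equal(
    cluster_by_threshold(c("AAAA", "AAAB", "AABB"), 1),
    c(1, 1, 1)), TRUE)  # chaining via single linkage
  expect_equal(cluster_by_threshold(c("AAAA", "TTTT", "GGGG"), 0.5),
               1:3)  # threshold below every distance: all singletons
  # randomized property vs the BFS oracle
  set.seed(17)
  for (trial in 1:25) {
    n <- sample(2:40, 1)
    len <- sample(c(4, 6, 9), 1)
    strings <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C"), len, replace = TRUE), collapse = "")
    }, character(1))
    th <- sample(0:len, 1)
    got <- cluster_by_threshold(strings, th)
    want <- oracle_cluster(strings, th)
    expect_true(partitions_equal(got, want))
    # relative mode agrees with the oracle too
    got_rel <- cluster_by_threshold(strings, th / len, relative = TRUE)
    want_rel <- oracle_cluster(strings, th / len, relative = TRUE)
    expect_true(partitions_equal(got_rel, want_rel))
  }
})

test_that("A1 groups identical junction AAs regardless of V gene", {
  rep <- make_rep(junction_aa = c("CARW", "CARW", "CAKW", "CTTW", "CAKW"),
                  v_call = c("IGHV1-1*01", "IGHV2-2*01", "IGHV1-1*01",
                             "IGHV1-1*01", "IGHV1-1*01"))
  p <- infer_A1(rep)
  expect_equal(length(unique(p$assignment)), 3)
  expect_equal(p$assignment[["s001"]], p$assignment[["s002"]])
})

test_that("A2 refines A1 by the V/J equality constraint", {
  rep <- make_rep(junction_aa = c("CARW", "CARW", "CAKW"),
                  v_call = c("IGHV1-1*01", "IGHV2-2*01", "IGHV1-1*01"))
  p1 <- infer_A1(rep)
  p2 <- infer_A2(rep)
  expect_equal(length(unique(p1$assignment)), 2)
  expect_equal(length(unique(p2$assignment)), 3)  # CARW split by V gene
  # every A2 cluster is a subset of one A1 cluster
  for (members in split(names(p2$assignment), p2$assignment)) {
    expect_equal(length(unique(p1$assignment[members])), 1)
  }
})

test_that("fixed-threshold approaches respect mode and boundary", {
  rep <- make_rep(junction_aa = c("CARDYW", "CARDFW", "CARNNW"))
  p3 <- infer("A3", rep)
  expect_equal(length(unique(p3$assignment)), 2)
  expect_equal(p3$params$threshold, 1)

  # 20-aa junctions: 3 differences (0.15) linked, 4 (0.20) not, at <= 0.15
  base <- "CARDYWGGGGSSSSTTTTTW"
  three <- "CARDYWGGGGSSSSTTAAAW"   # 3 mismatches
  four <- "CARDYWGGGGSSSSTAAAAW"    # 4 mismatches
  expect_equal(hamming(base, three), 3)
  expect_equal(hamming(base, four), 4)
  p_link <- infer("A4", make_rep(junction_aa = c(base, three)))
  expect_equal(length(unique(p_link$assignment)), 1)
  p_split <- infer("A4", make_rep(junction_aa = c(base, four)))
  expect_equal(length(unique(p_split$assignment)), 2)
})

test_that("A3 at threshold 0 reproduces A2 exactly", {
  for (seed in 1:5) {
    sim <- random_sim(200 + seed, n_clones = 10, depth = 50, rate = 0.02)
    p0 <- infer_fixed_threshold(sim$repertoire, "AA", "absolute", 0, "A3")
    p2 <- infer_A2(sim$repertoire)
    expect_equal(partition_signature(p0$assignment),
                 partition_signature(p2$assignment))
  }
})

test_that("clusters never cross VJ/junction-length boundaries", {
  sim <- random_sim(301, n_clones = 15, depth = 80, rate = 0.03)
  rec <- sim$repertoire$records
  key <- paste(strip_allele(rec$v_call), strip_allele(rec$j_call),
               nchar(rec$junction), sep = "|")
  names(key) <- rec$sequence_id
  for (a in c("A3", "A4", "A5")) {
    p <- infer(a, sim$repertoire)
    for (members in split(names(p$assignment), p$assignment)) {
      expect_equal(length(unique(key[members])), 1, info = a)
    }
  }
})

test_that("partitions are invariant to record order", {
  sim <- random_sim(302, n_clones = 10, depth = 60, rate = 0.02)
  rep <- sim$repertoire
  set.seed(1)
  shuffled <- as_repertoire(rep$records[sample(nrow(rep$records)), ])
  for (a in c("A1", "A2", "A4", "A5", "A6")) {
    p <- infer(a, rep)
    q <- infer(a, shuffled)
    expect_equal(partition_signature(p$assignment),
                 partition_signature(q$assignment), info = a)
  }
})

test_that("A6 threshold fitting finds the valley of bimodal distances", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    d <- pmin(pmax(c(rnorm(100, 0.03, 0.01), rnorm(100, 0.30, 0.05)), 0), 1)
    fit <- detect_bimodal_threshold(d)
    expect_true(fit$bimodal)
    if (fit$threshold > 0.08 && fit$threshold < 0.25) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("A6 falls back to 0.15 on degenerate distance distributions", {
  fit <- detect_bimodal_threshold(rep(0.2, 30))
  expect_false(fit$bimodal)
  expect_equal(fit$threshold, 0.15)
  # a repertoire of identical sequences within one group: one CF
  rep <- make_rep(junction = rep("TGTGCGAAATGG", 4),
                  junction_aa = rep("CAKW", 4))
  p <- infer_A6(rep)
  expect_equal(length(unique(p$assignment)), 1)
})

test_that("A6 errors when no group has two records", {
  rep <- make_rep(junction = c("TGTGCGTGG", "TGTGCGAAATGG"),
                  junction_aa = c("CAW", "CAKW"))
  expect_error(fit_sample_threshold(rep), "fixed threshold")
})

test_that("tf-idf vectors match a hand-computed toy corpus", {
  # corpus of 3 sequences, k = 2
  seqs <- c(a = "AAB", b = "AAC", c = "BBB")
  # 2-mers: a: AA, AB; b: AA, AC; c: BB x2
  v <- kmer_tfidf(seqs, k = 2)
  idf <- function(df) log(3 / df)
  expect_equal(v["a", "AA"], 1 * idf(2))
  expect_equal(v["a", "AB"], 1 * idf(1))
  expect_equal(v["b", "AC"], 1 * idf(1))
  expect_equal(v["c", "BB"], 2 * idf(1))
  expect_equal(v["c", "AA"], 0)
  # k-mer present in every sequence contributes nothing
  v2 <- kmer_tfidf(c(x = "AAT", y = "AAG"), k = 2)
  expect_equal(unname(v2[, "AA"]), c(0, 0))
  expect_error(kmer_tfidf(c(s = "ACG"), k = 4), "shorter than k")
})

test_that("A10 clusters by cosine distance with a negation threshold", {
  sim <- random_sim(303, n_clones = 8, depth = 40, rate = 0)
  neg <- random_sim(909, n_clones = 8, depth = 40, rate = 0)$repertoire
  p <- infer_A10(sim$repertoire, neg)
  expect_s3_class(p, "clonal_partition")
  expect_true(p$params$threshold >= 0)
  # identical sequences always co-cluster (cosine distance 0)
  rec <- sim$repertoire$records
  dup <- split(as.character(rec$sequence_id), rec$sequence)
  dup <- dup[lengths(dup) >= 2][[1]]
  expect_equal(length(unique(p$assignment[dup])), 1)
  # negation identical to the repertoire collapses the threshold to ~0
  p0 <- infer_A10(sim$repertoire, sim$repertoire)
  expect_lt(p0$params$threshold, 1e-10)
  expect_error(infer_A10(sim$repertoire, NULL), "negation")
})

test_that("the dispatcher applies table defaults and validates input", {
  sim <- random_sim(304, n_clones = 6, depth = 30)
  p3 <- infer("A3", sim$repertoire)
  expect_equal(p3$params[c("alphabet", "mode", "threshold")],
               list(alphabet = "AA", mode = "absolute", threshold = 1))
  p4 <- infer("A4", sim$repertoire)
  expect_equal(p4$params[c("alphabet", "mode", "threshold")],
               list(alphabet = "AA", mode = "relative", threshold = 0.15))
  p5 <- infer("A5", sim$repertoire)
  expect_equal(p5$params$alphabet, "NT")
  expect_error(infer("A7", sim$repertoire), "supported")
  expect_error(infer("A10", sim$repertoire), "negation")
})

test_that("CF count is non-increasing in the threshold (monotonicity)", {
  sim <- random_sim(305, n_clones = 12, depth = 70, rate = 0.02)
  n_cf <- vapply(c(0, 0.05, 0.1, 0.15, 0.25, 0.5), function(th) {
    p <- infer_fixed_threshold(sim$repertoire, "NT", "relative", th, "A5")
    length(unique(p$assignment))
  }, numeric(1))
  expect_true(all(diff(n_cf) <= 0))
})
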