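# Independent brute-force oracles and small fixture builders.

# Edge confusion by exhaustive enumeration of all unordered record pairs.
oracle_edge_confusion <- function(t_lab, i_lab) {
  ids <- names(t_lab)
  stopifnot(setequal(ids, names(i_lab)))
  tp <- fp <- tn <- fn <- 0
  n <- length(ids)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      same_t <- t_lab[ids[a]] == t_lab[ids[b]]
      same_i <- i_lab[ids[a]] == i_lab[ids[b]]
      if (same_t && same_i) tp <- tp + 1
      else if (!same_t && same_i) fp <- fp + 1
      else if (same_t && !same_i) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Same enumeration as oracle_edge_confusion, vectorized over the full pair
# matrix so large n stays fast; used by the bulk equivalence checks.
oracle_edge_confusion_outer <- function(t_lab, i_lab) {
  ids <- names(t_lab)
  i_lab <- i_lab[ids]
  same_t <- outer(t_lab, t_lab, "==")[upper.tri(diag(length(ids)))]
  same_i <- outer(i_lab, i_lab, "==")[upper.tri(diag(length(ids)))]
  list(tp = sum(same_t & same_i), fp = sum(!same_t & same_i),
       tn = sum(!same_t & !same_i), fn = sum(same_t & !same_i))
}

# Single-linkage clustering as transitive closure of the thresholded
# distance matrix, computed by breadth-first search.
oracle_cluster <- function(strings, threshold, relative = FALSE) {
  n <- length(strings)
  dist_ab <- function(a, b) {
    d <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (relative) d / nchar(a) else d
  }
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      adj[a, b] <- dist_ab(strings[a], strings[b]) <= threshold
    }
  }
  membership <- rep(NA_integer_, n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (!is.na(membership[start])) next
    comp <- comp + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(membership[v])) next
      membership[v] <- comp
      queue <- c(queue, which(adj[v, ] & is.na(membership)))
    }
  }
  membership
}

# TRUE when two membership vectors induce the same set partition.
partitions_equal <- function(a, b) {
  stopifnot(length(a) == length(b))
  groups_a <- split(seq_along(a), a)
  groups_b <- split(seq_along(b), b)
  sig <- function(g) sort(vapply(g, function(x) {
    paste(sort(x), collapse = ",")
  }, character(1)))
  identical(unname(sig(groups_a)), unname(sig(groups_b)))
}

# Canonical form of a partition for label-free comparison.
partition_signature <- function(assignment) {
  groups <- split(names(assignment), assignment)
  groups <- lapply(groups, sort)
  paste(sort(vapply(groups, paste, character(1), collapse = ",")),
        collapse = ";")
}

# Tiny repertoire with the given junction sequences (and optional fields).
make_rep <- function(junction_aa = NULL, junction = NULL,
                     v_call = "IGHV1-1*01", j_call = "IGHJ1*01", ...) {
  n <- max(length(junction_aa), length(junction))
  extra <- list(...)
  if (is.null(junction) && !is.null(junction_aa)) {
    junction <- vapply(junction_aa, function(aa) {
      paste(rep("NNN", nchar(aa)), collapse = "")
    }, character(1))
  }
  if (is.null(junction_aa)) junction_aa <- strrep("X", nchar(junction) %/% 3)
  df <- data.frame(sequence_id = sprintf("s%03d", seq_len(n)),
                   sample_id = "S1",
                   sequence = paste0("ACGTACGTAC", junction, "GGTACC"),
                   v_call = rep_len(v_call, n), j_call = rep_len(j_call, n),
                   junction = junction, junction_aa = junction_aa,
                   stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  as_repertoire(df)
}

# Random repertoire used by round-trip and order-invariance checks.
random_sim <- function(seed, n_clones = 15, depth = 60, rate = 0.01, ...) {
  simulate_repertoire(simulation_config(seed = seed, n_clones = n_clones,
                                        depth = depth,
                                        mutation_rate_per_site = rate, ...))
}

subset_truth <- function(truth, part) {
  new_clonal_partition("TRUE", truth$assignment[names(part$assignment)])
}
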