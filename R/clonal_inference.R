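#' Clonal partitions
#'
#' A `clonal_partition` records, for one inference approach, the mapping
#' from sequence id to clone label plus the resolved parameters that
#' produced it. Labels are opaque: only the induced set partition matters.
#'
#' @param approach_id one of `"A1"`, `"A2"`, `"A3"`, `"A4"`, `"A5"`,
#'   `"A6"`, `"A10"` or `"TRUE"` (ground truth).
#' @param assignment named character vector: `sequence_id -> clone label`.
#' @param params list of resolved parameters (thresholds, k, seeds).
#' @return a `clonal_partition` object.
#' @export
new_clonal_partition <- function(approach_id, assignment, params = list()) {
  stopifnot(is.character(assignment))
  if (is.null(names(assignment)) && length(assignment) > 0) {
    stop("assignment must be named by sequence_id", call. = FALSE)
  }
  if (anyDuplicated(names(assignment))) {
    stop("assignment must be single-valued per sequence_id", call. = FALSE)
  }
  structure(list(approach_id = approach_id, assignment = assignment,
                 params = params),
            class = "clonal_partition")
}

#' @export
print.clonal_partition <- function(x, ...) {
  cat(sprintf("<clonal_partition> %s: %d records in %d clonal families\n",
              x$approach_id, length(x$assignment),
              length(unique(x$assignment))))
  invisible(x)
}

#' Clone sizes of a partition
#' @param partition a [new_clonal_partition()] object.
#' @return named integer vector of clone sizes.
#' @export
clone_sizes <- function(partition) {
  stopifnot(inherits(partition, "clonal_partition"))
  tab <- table(partition$assignment)
  stats::setNames(as.integer(tab), names(tab))
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character strings of equal length.
#' @return integer count of mismatching positions.
#' @examples
#' hamming("CARDYW", "CARNNW")  # 2
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming distance requires equal-length strings (",
         nchar(a), " vs ", nchar(b), ")", call. = FALSE)
  }
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Length-normalized Hamming distance
#'
#' @inheritParams hamming
#' @return `hamming(a, b) / nchar(a)`, in `[0, 1]`.
#' @export
normalized_hamming <- function(a, b) {
  if (nchar(a) == 0) stop("zero-length strings", call. = FALSE)
  hamming(a, b) / nchar(a)
}

# Pairwise Hamming distance matrix for equal-length strings.
.hamming_matrix <- function(strings) {
  n <- length(strings)
  d <- matrix(0L, n, n)
  if (n < 2) return(d)
  chars <- matrix(unlist(strsplit(strings, "")), nrow = n, byrow = TRUE)
  for (col in seq_len(ncol(chars))) {
    d <- d + outer(chars[, col], chars[, col], "!=")
  }
  d
}

#' Partition a repertoire by V gene, J gene and junction length
#'
#' Groups records by the gene-level (allele-stripped, first-listed) V and J
#' calls and the junction length in the chosen alphabet — the pre-grouping
#' step shared by all VJ-partitioned approaches. Records missing a required
#' field are excluded.
#'
#' @param rep a [repertoire].
#' @param alphabet `"NT"` (junction nucleotides) or `"AA"` (junction amino
#'   acids; untranslatable records are excluded).
#' @return named list of integer row-index vectors into `rep$records`; names
#'   are `"Vgene|Jgene|length"` keys.
#' @export
partition_by_vj <- function(rep, alphabet = c("NT", "AA")) {
  alphabet <- match.arg(alphabet)
  rec <- rep$records
  seqs <- if (alphabet == "NT") as.character(rec$junction) else
    as.character(rec$junction_aa)
  usable <- !is.na(rec$v_call) & !is.na(rec$j_call) &
    !is.na(seqs) & nzchar(seqs)
  if (alphabet == "AA") usable <- usable & translatable(rep)
  idx <- which(usable)
  if (length(idx) == 0) return(list())
  key <- paste(strip_allele(rec$v_call[idx]),
               strip_allele(rec$j_call[idx]),
               nchar(seqs[idx]), sep = "|")
  split(idx, key)
}

#' Single-linkage clustering at a distance threshold
#'
#' Builds the fully connected graph over the records, removes every edge
#' whose distance exceeds the threshold, and returns the connected
#' components (so linkage is transitive: a chain of near neighbours joins
#' one family).
#'
#' @param strings equal-length sequences to cluster.
#' @param threshold maximum distance for an edge to be kept (edges satisfy
#'   `distance <= threshold`).
#' @param relative if TRUE the distance is the length-normalized Hamming
#'   distance, otherwise the absolute Hamming distance.
#' @return integer vector of component memberships (1-based).
#' @examples
#' cluster_by_threshold(c("CARDYW", "CARDFW", "CARNNW"), 1, relative = FALSE)
#' @export
cluster_by_threshold <- function(strings, threshold, relative = FALSE) {
  n <- length(strings)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  d <- .hamming_matrix(strings)
  if (relative) d <- d / nchar(strings[1])
  adj <- d <= threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  as.integer(igraph::components(g)$membership)
}

# Assemble a clonal_partition from per-group memberships.
.assemble_partition <- function(approach_id, rec, groups, memberships,
                                params) {
  assignment <- character(0)
  for (key in names(groups)) {
    idx <- groups[[key]]
    labels <- sprintf("%s|%d", key, memberships[[key]])
    assignment[as.character(rec$sequence_id[idx])] <- labels
  }
  # relabel to opaque sequential ids for stability under key renaming
  lev <- unique(assignment[order(names(assignment))])
  relab <- stats::setNames(sprintf("%s_%05d", approach_id, seq_along(lev)),
                           lev)
  new_clonal_partition(approach_id, stats::setNames(
    unname(relab[assignment]), names(assignment)), params)
}

#' Approach A1: identical junction amino-acid sequences
#'
#' Clusters records with an identical `junction_aa`, with no VJ
#' partitioning — the "unique junctions" reference approach.
#'
#' @param rep a [repertoire].
#' @return a [new_clonal_partition()].
#' @export
infer_A1 <- function(rep) {
  rec <- rep$records
  usable <- which(translatable(rep))
  aa <- as.character(rec$junction_aa[usable])
  .assemble_partition("A1", rec, list(all = usable),
                      list(all = as.integer(factor(aa, levels = unique(aa)))),
                      params = list())
}

#' Approach A2: subclones (identical V gene, J gene and junction AA)
#'
#' @param rep a [repertoire].
#' @return a [new_clonal_partition()].
#' @export
infer_A2 <- function(rep) {
  rec <- rep$records
  usable <- which(translatable(rep) & !is.na(rec$v_call) &
                    !is.na(rec$j_call))
  key <- paste(strip_allele(rec$v_call[usable]),
               strip_allele(rec$j_call[usable]),
               as.character(rec$junction_aa[usable]), sep = "|")
  .assemble_partition("A2", rec, list(all = usable),
                      list(all = as.integer(factor(key,
                                                   levels = unique(key)))),
                      params = list())
}

#' Fixed-threshold clonal family inference (approaches A3, A4, A5)
#'
#' Within each VJ/junction-length group, clusters junctions by
#' single-linkage at a fixed Hamming-distance threshold: absolute (maximum
#' number of differing positions) or relative (maximum fraction of
#' differing positions). Table defaults: A3 = AA, absolute 1; A4 = AA,
#' relative 0.15; A5 = NT, relative 0.15.
#'
#' @param rep a [repertoire].
#' @param alphabet `"NT"` or `"AA"`.
#' @param mode `"absolute"` or `"relative"`.
#' @param threshold non-negative distance threshold.
#' @param approach_id label recorded on the partition.
#' @return a [new_clonal_partition()].
#' @export
infer_fixed_threshold <- function(rep, alphabet = c("AA", "NT"),
                                  mode = c("absolute", "relative"),
                                  threshold,
                                  approach_id = "A3") {
  alphabet <- match.arg(alphabet)
  mode <- match.arg(mode)
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  rec <- rep$records
  groups <- partition_by_vj(rep, alphabet)
  seqs <- if (alphabet == "NT") as.character(rec$junction) else
    as.character(rec$junction_aa)
  memberships <- lapply(groups, function(idx) {
    cluster_by_threshold(seqs[idx], threshold,
                         relative = mode == "relative")
  })
  .assemble_partition(approach_id, rec, groups, memberships,
                      params = list(alphabet = alphabet, mode = mode,
                                    threshold = threshold))
}

#' Distance-to-nearest distribution and sample-specific threshold (A6)
#'
#' For every record, computes the normalized Hamming distance to its
#' nearest non-identical neighbour within its VJ/junction-length group
#' (junction nucleotides). A Gaussian kernel density (Silverman bandwidth,
#' 512-point grid on `[0, 1]`) is fitted to these distances; when the
#' density is bimodal the threshold is placed at the density minimum
#' between the two highest local maxima, otherwise a documented fallback
#' of 0.15 is used.
#'
#' @param rep a [repertoire].
#' @param fallback threshold used when no bimodal structure is found.
#' @return a `threshold_fit`: list with `nearest_distances`, `bandwidth`,
#'   `density_grid` (data.frame `x`, `density`), `threshold`, `bimodal`.
#' @export
fit_sample_threshold <- function(rep, fallback = 0.15) {
  rec <- rep$records
  groups <- partition_by_vj(rep, "NT")
  if (all(lengths(groups) < 2)) {
    stop("no VJ/junction-length group has >= 2 records; ",
         "use a fixed threshold instead", call. = FALSE)
  }
  seqs <- as.character(rec$junction)
  dists <- numeric(0)
  for (idx in groups[lengths(groups) >= 2]) {
    d <- .hamming_matrix(seqs[idx]) / nchar(seqs[idx][1])
    for (r in seq_along(idx)) {
      others <- d[r, -r]
      others <- others[others > 0]  # nearest *non-identical* neighbour
      if (length(others) > 0) dists <- c(dists, min(others))
    }
  }
  fit <- detect_bimodal_threshold(dists, fallback = fallback)
  fit$nearest_distances <- dists
  fit
}

#' Locate the valley of a bimodal distance distribution
#'
#' @param distances numeric vector of nearest-neighbour distances in
#'   `[0, 1]`.
#' @param fallback value returned when fewer than two density maxima exist.
#' @return a `threshold_fit` (see [fit_sample_threshold()]).
#' @export
detect_bimodal_threshold <- function(distances, fallback = 0.15) {
  degenerate <- length(distances) < 5 ||
    length(unique(round(distances, 12))) < 2
  if (degenerate) {
    return(structure(list(nearest_distances = distances,
                          bandwidth = NA_real_, density_grid = NULL,
                          threshold = fallback, bimodal = FALSE),
                     class = "threshold_fit"))
  }
  dens <- stats::density(distances, bw = "nrd0", n = 512, from = 0, to = 1)
  y <- dens$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  # include boundary maxima
  is_max[1] <- y[1] > y[2]
  is_max[n] <- y[n] > y[n - 1]
  peaks <- which(is_max)
  if (length(peaks) < 2) {
    return(structure(list(nearest_distances = distances,
                          bandwidth = dens$bw,
                          density_grid = data.frame(x = dens$x, density = y),
                          threshold = fallback, bimodal = FALSE),
                     class = "threshold_fit"))
  }
  top2 <- sort(peaks[order(-y[peaks])][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1
  structure(list(nearest_distances = distances, bandwidth = dens$bw,
                 density_grid = data.frame(x = dens$x, density = y),
                 threshold = dens$x[valley], bimodal = TRUE),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> threshold = %.4f (%s; %d distances)\n",
              x$threshold, if (x$bimodal) "bimodal" else "fallback",
              length(x$nearest_distances)))
  invisible(x)
}

#' Approach A6: sample-specific distance-to-nearest threshold
#'
#' Fits the per-sample threshold with [fit_sample_threshold()] and then
#' clusters exactly as A5 (nucleotide junctions, relative threshold).
#'
#' @param rep a [repertoire].
#' @param threshold optional forced threshold (skips the fit).
#' @param fallback fallback threshold when the distance-to-nearest
#'   distribution is not bimodal.
#' @return a [new_clonal_partition()]; `params$fit` holds the
#'   `threshold_fit` when one was computed.
#' @export
infer_A6 <- function(rep, threshold = NULL, fallback = 0.15) {
  fit <- NULL
  if (is.null(threshold)) {
    fit <- fit_sample_threshold(rep, fallback = fallback)
    threshold <- fit$threshold
  }
  part <- infer_fixed_threshold(rep, "NT", "relative", threshold,
                                approach_id = "A6")
  part$params$fit <- fit
  part$params$threshold <- threshold
  part
}

#' tf-idf weighted k-mer vectors over full sequences
#'
#' Represents each record's full nucleotide sequence as a vector of k-mer
#' counts weighted by inverse document frequency `ln(N / df)`, where `df`
#' is the number of sequences containing the k-mer. K-mers present in every
#' sequence receive weight zero.
#'
#' @param sequences character vector of sequences (named by sequence id).
#' @param k k-mer length (default 4).
#' @return numeric matrix, one row per sequence, columns = observed k-mers.
#' @export
kmer_tfidf <- function(sequences, k = 4) {
  if (any(nchar(sequences) < k)) {
    stop("sequence(s) shorter than k = ", k, ": ",
         paste(utils::head(names(sequences)[nchar(sequences) < k], 5),
               collapse = ", "), call. = FALSE)
  }
  counts <- lapply(sequences, function(s) {
    n <- nchar(s) - k + 1
    table(substring(s, seq_len(n), seq_len(n) + k - 1))
  })
  kmers <- sort(unique(unlist(lapply(counts, names))))
  tf <- matrix(0, nrow = length(sequences), ncol = length(kmers),
               dimnames = list(names(sequences), kmers))
  for (i in seq_along(counts)) {
    tf[i, names(counts[[i]])] <- as.numeric(counts[[i]])
  }
  df <- colSums(tf > 0)
  idf <- log(length(sequences) / df)
  sweep(tf, 2, idf, `*`)
}

# Cosine distance between the rows of x and the rows of y.
.cosine_distance <- function(x, y) {
  nx <- sqrt(rowSums(x^2))
  ny <- sqrt(rowSums(y^2))
  sim <- tcrossprod(x, y) / outer(pmax(nx, .Machine$double.eps),
                                  pmax(ny, .Machine$double.eps))
  d <- 1 - sim
  # zero-norm vectors are orthogonal to everything by convention
  d[nx == 0, ] <- 1
  d[, ny == 0] <- 1
  pmin(pmax(d, 0), 2)
}

#' Approach A10: alignment-free tf-idf clustering with negation threshold
#'
#' Represents full sequences as tf-idf weighted k-mer vectors (no VJ
#' partitioning, no length matching) and clusters them by cosine distance.
#' The clonal threshold is calibrated by negation: distances from each
#' repertoire sequence to its nearest sequence in a repertoire from a
#' different individual are computed, and the threshold is set to the
#' `negation_fraction` quantile of those distances.
#'
#' @param rep a [repertoire].
#' @param negation a [repertoire] from a different sample/subject.
#' @param k k-mer length (default 4).
#' @param negation_fraction quantile of nearest-negation distances used as
#'   the clonal threshold (default 0.10).
#' @return a [new_clonal_partition()]; `params` records `k`, the fraction
#'   and the resolved `threshold`.
#' @export
infer_A10 <- function(rep, negation, k = 4, negation_fraction = 0.10) {
  if (missing(negation) || is.null(negation) || n_records(negation) == 0) {
    stop("A10 requires a non-empty negation repertoire from a different ",
         "individual", call. = FALSE)
  }
  rec <- rep$records
  seqs <- stats::setNames(as.character(rec$sequence),
                          as.character(rec$sequence_id))
  neg <- stats::setNames(as.character(negation$records$sequence),
                         paste0("NEG:", negation$records$sequence_id))
  all_v <- kmer_tfidf(c(seqs, neg), k = k)
  v_rep <- all_v[seq_along(seqs), , drop = FALSE]
  v_neg <- all_v[length(seqs) + seq_along(neg), , drop = FALSE]
  nearest_neg <- apply(.cosine_distance(v_rep, v_neg), 1, min)
  threshold <- unname(stats::quantile(nearest_neg, negation_fraction))
  d <- .cosine_distance(v_rep, v_rep)
  g <- igraph::graph_from_adjacency_matrix(d <= threshold,
                                           mode = "undirected", diag = FALSE)
  membership <- as.integer(igraph::components(g)$membership)
  new_clonal_partition(
    "A10",
    stats::setNames(sprintf("A10_%05d", membership), names(seqs)),
    params = list(k = k, negation_fraction = negation_fraction,
                  threshold = threshold))
}

#' Infer clonal families with a named approach
#'
#' Dispatcher over the implemented approaches with their standard default
#' parameters:
#' \describe{
#'   \item{A1}{identical junction AA, no VJ partitioning}
#'   \item{A2}{identical V gene + J gene + junction AA (subclones)}
#'   \item{A3}{VJ partition, junction AA, absolute Hamming threshold 1}
#'   \item{A4}{VJ partition, junction AA, relative threshold 0.15}
#'   \item{A5}{VJ partition, junction NT, relative threshold 0.15}
#'   \item{A6}{VJ partition, junction NT, sample-specific threshold from
#'     the bimodal distance-to-nearest distribution}
#'   \item{A10}{alignment-free tf-idf k-mer cosine clustering with
#'     negation-calibrated threshold}
#' }
#'
#' @param approach_id approach name, see Details.
#' @param rep a [repertoire].
#' @param config list of overrides: `threshold`, `alphabet`, `mode`,
#'   `fallback`, `negation`, `k`, `negation_fraction`.
#' @return a [new_clonal_partition()].
#' @examples
#' sim <- simulate_repertoire(simulation_config(seed = 2, n_clones = 20,
#'                                              depth = 80))
#' p <- infer("A4", sim$repertoire)
#' length(unique(p$assignment))
#' @export
infer <- function(approach_id, rep, config = list()) {
  supported <- c("A1", "A2", "A3", "A4", "A5", "A6", "A10")
  if (!approach_id %in% supported) {
    stop("unknown approach '", approach_id, "'; supported: ",
         paste(supported, collapse = ", "), call. = FALSE)
  }
  th <- function(default) {
    if (!is.null(config$threshold)) config$threshold else default
  }
  switch(approach_id,
         A1 = infer_A1(rep),
         A2 = infer_A2(rep),
         A3 = infer_fixed_threshold(rep, "AA", "absolute", th(1), "A3"),
         A4 = infer_fixed_threshold(rep, "AA", "relative", th(0.15), "A4"),
         A5 = infer_fixed_threshold(rep, "NT", "relative", th(0.15), "A5"),
         A6 = infer_A6(rep, threshold = config$threshold,
                       fallback = if (!is.null(config$fallback))
                         config$fallback else 0.15),
         A10 = {
           if (is.null(config$negation)) {
             stop("A10 requires config$negation (a repertoire from a ",
                  "different individual)", call. = FALSE)
           }
           infer_A10(rep, config$negation,
                     k = if (!is.null(config$k)) config$k else 4,
                     negation_fraction =
                       if (!is.null(config$negation_fraction))
                         config$negation_fraction else 0.10)
         })
}
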