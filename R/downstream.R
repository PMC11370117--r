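#' Merge repertoires from several samples
#'
#' Concatenates repertoires while keeping each record's sample annotation,
#' the first step of the shared-clonal-family analysis. Sample ids must be
#' pairwise disjoint across inputs; colliding sequence ids are made unique
#' by prefixing with the record's sample id.
#'
#' @param reps list of [repertoire] objects.
#' @return a single merged [repertoire].
#' @export
merge_samples <- function(reps) {
  stopifnot(length(reps) >= 1, all(vapply(reps, inherits, logical(1),
                                          "repertoire")))
  if (length(reps) == 1) return(reps[[1]])
  sids <- lapply(reps, sample_ids)
  for (i in seq_along(sids)) {
    for (j in seq_len(i - 1)) {
      overlap <- intersect(sids[[i]], sids[[j]])
      if (length(overlap) > 0) {
        stop("sample_id collision between inputs: ",
             paste(overlap, collapse = ", "), call. = FALSE)
      }
    }
  }
  recs <- lapply(reps, function(r) r$records)
  cols <- Reduce(union, lapply(recs, names))
  recs <- lapply(recs, function(r) {
    for (col in setdiff(cols, names(r))) r[[col]] <- rep(NA, nrow(r))
    r[, cols, drop = FALSE]
  })
  merged <- do.call(rbind, recs)
  if (anyDuplicated(merged$sequence_id)) {
    merged$sequence_id <- paste(merged$sample_id, merged$sequence_id,
                                sep = ":")
    if (anyDuplicated(merged$sequence_id)) {
      stop("sequence ids remain duplicated after sample prefixing",
           call. = FALSE)
    }
  }
  rownames(merged) <- NULL
  as_repertoire(merged, provenance = paste0(
    "merge_samples(", length(reps), " repertoires)"))
}

#' Shared clonal families across samples
#'
#' A clonal family is shared when its members originate from two or more
#' samples of the merged repertoire. Dominance of shared families is
#' assessed on the merged repertoire's clone frequencies.
#'
#' @param partition a [new_clonal_partition()] over the merged repertoire.
#' @param merged_rep the merged [repertoire] (needs >= 2 samples).
#' @param dominant_threshold frequency above which a clone is dominant.
#' @return a `shared_clone_report`: list with `n_cf_total`, `n_shared`,
#'   `shared_fraction`, `per_pair_counts` (data.frame `sample_a`,
#'   `sample_b`, `n_shared`), `n_shared_dominant` and `shared_labels`.
#' @export
shared_clones <- function(partition, merged_rep,
                          dominant_threshold = 0.005) {
  stopifnot(inherits(partition, "clonal_partition"))
  samples <- sample_ids(merged_rep)
  if (length(samples) < 2) {
    stop("shared-clone analysis requires >= 2 samples", call. = FALSE)
  }
  rec <- merged_rep$records
  sample_of <- stats::setNames(as.character(rec$sample_id),
                               as.character(rec$sequence_id))
  ids <- names(partition$assignment)
  clone_samples <- tapply(sample_of[ids], partition$assignment,
                          function(x) sort(unique(x)))
  shared <- names(clone_samples)[lengths(clone_samples) >= 2]
  pairs <- t(utils::combn(sort(samples), 2))
  per_pair <- data.frame(sample_a = pairs[, 1], sample_b = pairs[, 2],
                         n_shared = vapply(seq_len(nrow(pairs)),
                                           function(r) {
    sum(vapply(clone_samples[shared], function(s) {
      all(pairs[r, ] %in% s)
    }, logical(1)))
  }, numeric(1)), stringsAsFactors = FALSE)
  f <- clonal_frequencies(partition)
  dom <- dominant_clones(f, dominant_threshold)
  structure(list(n_cf_total = length(clone_samples),
                 n_shared = length(shared),
                 shared_fraction = length(shared) / length(clone_samples),
                 per_pair_counts = per_pair,
                 n_shared_dominant = length(intersect(shared, dom)),
                 shared_labels = shared),
            class = "shared_clone_report")
}

#' @export
print.shared_clone_report <- function(x, ...) {
  cat(sprintf("<shared_clone_report> %d/%d CFs shared (%.1f%%), %d dominant\n",
              x$n_shared, x$n_cf_total, 100 * x$shared_fraction,
              x$n_shared_dominant))
  invisible(x)
}

#' Heavy/light-chain concordance of a partition
#'
#' A heavy-chain clonal family is concordant when all of its members pair
#' to the same light-chain V/J genes (gene-level, allele-stripped);
#' singletons are concordant by definition. Families containing a record
#' without light-chain calls are unevaluable and excluded from the
#' denominator (their count is reported).
#'
#' @param rep a [repertoire] whose records carry `lc_v_call`/`lc_j_call`.
#' @param partition a [new_clonal_partition()] over `rep`.
#' @return a `concordance_report`: list with `n_cf` (evaluable families),
#'   `n_concordant`, `concordance` and `n_unevaluable`.
#' @export
lc_concordance <- function(rep, partition) {
  stopifnot(inherits(partition, "clonal_partition"))
  rec <- rep$records
  lc_v <- stats::setNames(as.character(rec$lc_v_call),
                          as.character(rec$sequence_id))
  lc_j <- stats::setNames(as.character(rec$lc_j_call),
                          as.character(rec$sequence_id))
  ids <- names(partition$assignment)
  clones <- split(ids, partition$assignment)
  evaluable <- 0L
  concordant <- 0L
  unevaluable <- 0L
  for (members in clones) {
    v <- lc_v[members]
    j <- lc_j[members]
    if (any(is.na(v) | is.na(j))) {
      unevaluable <- unevaluable + 1L
      next
    }
    evaluable <- evaluable + 1L
    pairs <- unique(paste(strip_allele(v), strip_allele(j), sep = "|"))
    if (length(pairs) == 1) concordant <- concordant + 1L
  }
  if (evaluable == 0) {
    stop("no clonal family has complete light-chain calls", call. = FALSE)
  }
  structure(list(n_cf = evaluable, n_concordant = concordant,
                 concordance = concordant / evaluable,
                 n_unevaluable = unevaluable),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "<concordance_report> %d/%d CFs concordant (%.1f%%), %d unevaluable\n",
    x$n_concordant, x$n_cf, 100 * x$concordance, x$n_unevaluable))
  invisible(x)
}
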