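#' Clonal frequency distribution of a partition
#'
#' Frequencies count rearrangement records (rows), matching the definition
#' of a clone's frequency as the number of BCR sequences it includes; a
#' distinct-sequence mode is available via `distinct`.
#'
#' @param partition a [new_clonal_partition()].
#' @param rep optional [repertoire]; required for `distinct = TRUE`.
#' @param distinct if TRUE, count distinct nucleotide sequences per clone
#'   instead of records.
#' @return a `clonal_frequencies` object: list with `sizes` (named integer),
#'   `total` and `frequencies`.
#' @export
clonal_frequencies <- function(partition, rep = NULL, distinct = FALSE) {
  stopifnot(inherits(partition, "clonal_partition"))
  if (length(partition$assignment) == 0) {
    stop("cannot compute frequencies of an empty partition", call. = FALSE)
  }
  if (distinct) {
    if (is.null(rep)) stop("distinct = TRUE requires `rep`", call. = FALSE)
    rec <- rep$records
    seqs <- stats::setNames(as.character(rec$sequence),
                            as.character(rec$sequence_id))
    ids <- names(partition$assignment)
    sizes <- tapply(seqs[ids], partition$assignment,
                    function(x) length(unique(x)))
    sizes <- stats::setNames(as.integer(sizes), names(sizes))
  } else {
    sizes <- clone_sizes(partition)
  }
  total <- sum(sizes)
  structure(list(sizes = sizes, total = total,
                 frequencies = sizes / total),
            class = "clonal_frequencies")
}

#' @export
print.clonal_frequencies <- function(x, ...) {
  cat(sprintf("<clonal_frequencies> %d clones over %d records\n",
              length(x$sizes), x$total))
  invisible(x)
}

#' Hill diversity of order alpha
#'
#' The Hill number `(sum f_i^alpha)^(1/(1-alpha))` — the effective number
#' of equally-frequent clones. `alpha = 0` gives richness, `alpha = 2` the
#' inverse Simpson index; the `alpha -> 1` limit is `exp(Shannon)` and is
#' delegated to [shannon_index()].
#'
#' @param f a [clonal_frequencies()] object.
#' @param alpha diversity order, `>= 0` and `!= 1`.
#' @return the Hill diversity (effective clone count).
#' @examples
#' p <- new_clonal_partition("TRUE",
#'   stats::setNames(c("c1", "c1", "c2", "c3"), paste0("s", 1:4)))
#' hill_diversity(clonal_frequencies(p), 2)  # 8/3
#' @export
hill_diversity <- function(f, alpha) {
  stopifnot(inherits(f, "clonal_frequencies"), alpha >= 0)
  if (alpha == 1) {
    stop("alpha = 1 is the Shannon limit; use exp(shannon_index(f))",
         call. = FALSE)
  }
  sum(f$frequencies^alpha)^(1 / (1 - alpha))
}

#' Shannon diversity index
#'
#' `-sum f_i ln f_i`, the natural-log (`alpha -> 1`) Hill limit. Ranges
#' from 0 (one clone) to `ln(number of clones)` (uniform clone sizes).
#'
#' @param f a [clonal_frequencies()] object.
#' @param base_log `"nats"` (natural log, default) or `"bits"` (log2).
#' @return the Shannon index.
#' @export
shannon_index <- function(f, base_log = c("nats", "bits")) {
  base_log <- match.arg(base_log)
  stopifnot(inherits(f, "clonal_frequencies"))
  p <- f$frequencies
  h <- -sum(p * log(p))
  if (base_log == "bits") h / log(2) else h
}

#' Gini-Simpson diversity index
#'
#' `1 - sum f_i^2`: the probability that two randomly selected sequences
#' belong to different clonal families. Equals `1 - 1/D` where `D` is the
#' order-2 Hill diversity.
#'
#' @param f a [clonal_frequencies()] object.
#' @return value in `[0, 1]`.
#' @export
gini_simpson <- function(f) {
  stopifnot(inherits(f, "clonal_frequencies"))
  1 - sum(f$frequencies^2)
}

#' Dominant clonal families
#'
#' Clones whose record frequency is strictly above the threshold
#' (default 0.5% of the repertoire).
#'
#' @param f a [clonal_frequencies()] object.
#' @param freq_threshold frequency cut-off in `(0, 1)`.
#' @return character vector of dominant clone labels.
#' @export
dominant_clones <- function(f, freq_threshold = 0.005) {
  stopifnot(inherits(f, "clonal_frequencies"))
  if (freq_threshold <= 0 || freq_threshold >= 1) {
    stop("freq_threshold must lie in (0, 1)", call. = FALSE)
  }
  names(f$frequencies)[f$frequencies > freq_threshold]
}

#' D50: clones accounting for half the repertoire
#'
#' The smallest number of clonal families whose summed sizes cover at
#' least 50% of records; ties between equal-sized clones are broken by
#' label order, making the value deterministic.
#'
#' @param f a [clonal_frequencies()] object.
#' @return positive integer.
#' @export
d50 <- function(f) {
  stopifnot(inherits(f, "clonal_frequencies"))
  ord <- order(-f$sizes, names(f$sizes))
  cum <- cumsum(f$sizes[ord])
  as.integer(which(cum >= f$total / 2)[1])
}

#' Number of singleton clonal families
#'
#' @param partition a [new_clonal_partition()].
#' @return count of clones of size exactly 1.
#' @export
count_singletons <- function(partition) {
  sum(clone_sizes(partition) == 1)
}

#' Mean somatic mutation load of a repertoire
#'
#' Percentage of mutated nucleotides outside the junction, averaged over
#' records: `100 * (v_mutation_count + j_mutation_count) /
#' (v_alignment_length + j_alignment_length)`.
#'
#' @param rep a [repertoire].
#' @return mean mutation load in percent.
#' @export
mutation_load <- function(rep) {
  rec <- rep$records
  ok <- !is.na(rec$v_mutation_count) & !is.na(rec$j_mutation_count) &
    !is.na(rec$v_alignment_length) & !is.na(rec$j_alignment_length)
  if (!any(ok)) {
    stop("no records carry mutation counts and alignment lengths",
         call. = FALSE)
  }
  if (any(!ok)) {
    warning(sum(!ok), " record(s) without mutation counts were skipped")
  }
  loads <- 100 * (rec$v_mutation_count[ok] + rec$j_mutation_count[ok]) /
    (rec$v_alignment_length[ok] + rec$j_alignment_length[ok])
  mean(loads)
}

#' Summarize a partition with the standard outcome measures
#'
#' Computes the eight repertoire outcome measures from one clonal frequency
#' distribution: number of clonal families, singletons, mean and maximum
#' family size, dominant families, D50, Shannon and Gini-Simpson indices.
#'
#' @param partition a [new_clonal_partition()].
#' @param rep optional [repertoire]; when supplied with mutation counts,
#'   `mutation_load` is included.
#' @param freq_threshold dominance threshold passed to [dominant_clones()].
#' @return a one-row data.frame of outcome measures.
#' @export
summarize_outcomes <- function(partition, rep = NULL,
                               freq_threshold = 0.005) {
  f <- clonal_frequencies(partition)
  out <- data.frame(
    approach = partition$approach_id,
    n_cf = length(f$sizes),
    n_singletons = count_singletons(partition),
    mean_size = f$total / length(f$sizes),
    max_size = max(f$sizes),
    n_dominant = length(dominant_clones(f, freq_threshold)),
    d50 = d50(f),
    shannon = shannon_index(f),
    gini_simpson = gini_simpson(f),
    stringsAsFactors = FALSE)
  if (!is.null(rep) && any(!is.na(rep$records$v_mutation_count))) {
    out$mutation_load <- mutation_load(rep)
  }
  out
}
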