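#' Clique edges of a clonal partition
#'
#' Represents each clonal family as a fully connected graph of its member
#' sequences: every unordered pair of records sharing a clone label is one
#' edge. Singleton families contribute no edges.
#'
#' @param partition a [new_clonal_partition()].
#' @return character vector of canonical `"id1||id2"` edge keys
#'   (lexicographically ordered within each pair).
#' @export
clone_edges <- function(partition) {
  stopifnot(inherits(partition, "clonal_partition"))
  ids <- names(partition$assignment)
  out <- character(0)
  for (members in split(ids, partition$assignment)) {
    if (length(members) < 2) next
    members <- sort(members)
    pairs <- utils::combn(members, 2)
    out <- c(out, paste(pairs[1, ], pairs[2, ], sep = "||"))
  }
  out
}

#' Edge-based confusion counts between two partitions
#'
#' Compares the clique edges of the ground-truth and inferred partitions
#' over the universe of all `C(n, 2)` unordered record pairs:
#' TP = pairs co-clustered in both, FP = co-clustered only in the
#' inference, FN = co-clustered only in the truth, TN = the remainder.
#' TP/FP/FN are computed from the truth-by-inference contingency counts;
#' TN follows algebraically from the pair-universe total.
#'
#' @param truth,inferred [new_clonal_partition()] objects covering the
#'   identical set of sequence ids.
#' @return an `edge_confusion` object: list with `tp`, `fp`, `tn`, `fn`
#'   and `n_records`.
#' @examples
#' t <- new_clonal_partition("TRUE",
#'   stats::setNames(c("x", "x", "x", "y"), c("a", "b", "c", "d")))
#' i <- new_clonal_partition("A1",
#'   stats::setNames(c("p", "p", "q", "q"), c("a", "b", "c", "d")))
#' edge_confusion(t, i)  # tp 1, fp 1, fn 2, tn 2
#' @export
edge_confusion <- function(truth, inferred) {
  stopifnot(inherits(truth, "clonal_partition"),
            inherits(inferred, "clonal_partition"))
  ids_t <- names(truth$assignment)
  ids_i <- names(inferred$assignment)
  if (!setequal(ids_t, ids_i)) {
    diff <- c(setdiff(ids_t, ids_i), setdiff(ids_i, ids_t))
    stop("partitions cover different records; symmetric difference: ",
         paste(utils::head(diff, 10), collapse = ", "),
         if (length(diff) > 10) " ..." else "", call. = FALSE)
  }
  n <- length(ids_t)
  t_lab <- truth$assignment[ids_t]
  i_lab <- inferred$assignment[ids_t]
  pairs2 <- function(x) sum(choose(as.numeric(table(x)), 2))
  tp <- pairs2(paste(t_lab, i_lab, sep = "\r"))
  edges_t <- pairs2(t_lab)
  edges_i <- pairs2(i_lab)
  fp <- edges_i - tp
  fn <- edges_t - tp
  tn <- choose(n, 2) - tp - fp - fn
  stopifnot(tp + fp + tn + fn == choose(n, 2))
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n_records = n),
            class = "edge_confusion")
}

#' @export
print.edge_confusion <- function(x, ...) {
  cat(sprintf("<edge_confusion> n=%d  TP=%g FP=%g FN=%g TN=%g\n",
              x$n_records, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Performance measures from edge confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, F1
#' `2TP/(2TP+FP+FN)`, Jaccard `TP/(TP+FN+FP)`, accuracy
#' `(TP+TN)/(TP+TN+FP+FN)` and specificity `TN/(TN+FP)`. Ratios with a
#' zero denominator are reported as `NA` (undefined), never silently as 0
#' or 1.
#'
#' @param confusion an [edge_confusion()] object.
#' @return a `performance_report`: one-row data.frame of the six measures.
#' @export
performance <- function(confusion) {
  stopifnot(inherits(confusion, "edge_confusion"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  with(confusion, structure(data.frame(
    sensitivity = ratio(tp, tp + fn),
    precision = ratio(tp, tp + fp),
    f1 = ratio(2 * tp, 2 * tp + fp + fn),
    jaccard = ratio(tp, tp + fn + fp),
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    specificity = ratio(tn, tn + fp)),
    class = c("performance_report", "data.frame")))
}

#' Evaluate several inference approaches against the ground truth
#'
#' Runs each requested approach on a simulated repertoire carrying
#' `clone_id_true`, computes edge-based confusion and performance against
#' the true partition, and appends the approach's outcome measures. A
#' failing approach yields a row with an `error` message rather than
#' aborting the table.
#'
#' @param rep a [repertoire] whose records carry `clone_id_true`.
#' @param approaches character vector of approach ids (see [infer()]).
#' @param configs named list of per-approach config lists (e.g.
#'   `list(A10 = list(negation = other_rep))`).
#' @return data.frame with one row per approach: confusion counts,
#'   performance measures, outcome measures, and `error` (NA on success).
#' @export
evaluate_approaches <- function(rep, approaches, configs = list()) {
  rec <- rep$records
  if (all(is.na(rec$clone_id_true))) {
    stop("repertoire carries no clone_id_true ground truth", call. = FALSE)
  }
  truth <- new_clonal_partition(
    "TRUE", stats::setNames(as.character(rec$clone_id_true),
                            as.character(rec$sequence_id)))
  rows <- lapply(approaches, function(a) {
    base <- data.frame(approach = a, stringsAsFactors = FALSE)
    res <- tryCatch({
      part <- infer(a, rep, config = if (!is.null(configs[[a]]))
        configs[[a]] else list())
      # evaluate on the records the approach analysed
      sub_truth <- new_clonal_partition(
        "TRUE", truth$assignment[names(part$assignment)])
      conf <- edge_confusion(sub_truth, part)
      cbind(base,
            as.data.frame(conf[c("tp", "fp", "fn", "tn")]),
            performance(conf),
            summarize_outcomes(part)[, -1, drop = FALSE],
            data.frame(n_analyzed = length(part$assignment),
                       error = NA_character_, stringsAsFactors = FALSE))
    }, error = function(e) {
      cbind(base, data.frame(error = conditionMessage(e),
                             stringsAsFactors = FALSE))
    })
    res
  })
  # align columns across successful and failed rows
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (col in setdiff(cols, names(r))) r[[col]] <- rep(NA, nrow(r))
    r[, cols, drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' True partition of a simulated repertoire
#'
#' @param rep a [repertoire] with `clone_id_true` set.
#' @return the ground-truth [new_clonal_partition()].
#' @export
true_partition <- function(rep) {
  rec <- rep$records
  if (all(is.na(rec$clone_id_true))) {
    stop("repertoire carries no clone_id_true ground truth", call. = FALSE)
  }
  new_clonal_partition(
    "TRUE", stats::setNames(as.character(rec$clone_id_true),
                            as.character(rec$sequence_id)))
}
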