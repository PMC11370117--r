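#' Read an AIRR Rearrangement TSV
#'
#' Reads a tab-separated AIRR Rearrangement file into a [repertoire].
#' Records missing a junction or V/J call are routed to the `rejected`
#' element with a reason, never silently dropped; record order follows file
#' row order.
#'
#' @param path path to a tab-separated file with a header row containing at
#'   minimum `sequence_id`, `v_call`, `j_call`, `junction_aa`.
#' @param dialect input dialect; only `"airr_tsv"` is supported.
#' @return a [repertoire]; `rep$rejected` holds excluded rows with a
#'   `rejection_reason` column.
#' @seealso [write_rearrangements()]
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(paste(
#'   c("sequence_id\tv_call\tj_call\tjunction\tjunction_aa",
#'     "s1\tIGHV1-2*02\tIGHJ4*02\tTGTGCGAGATGG\tCARW"), collapse = "\n"), tsv)
#' rep <- read_rearrangements(tsv)
#' n_records(rep)
#' @export
read_rearrangements <- function(path, dialect = "airr_tsv") {
  dialect <- match.arg(dialect, "airr_tsv")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  need <- c("sequence_id", "v_call", "j_call", "junction_aa")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("AIRR TSV is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  # empty strings mark absent optional values
  for (col in names(tab)) tab[[col]][tab[[col]] == ""] <- NA
  for (col in c("v_mutation_count", "v_alignment_length",
                "j_mutation_count", "j_alignment_length")) {
    if (col %in% names(tab)) tab[[col]] <- as.integer(tab[[col]])
  }
  if (anyDuplicated(tab$sequence_id)) {
    dup <- unique(tab$sequence_id[duplicated(tab$sequence_id)])
    stop("duplicate sequence_id value(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(tab))
  blank <- function(x) is.na(x) | !nzchar(as.character(x))
  if ("junction" %in% names(tab)) {
    reason[blank(tab$junction) & blank(tab$junction_aa)] <-
      "missing junction"
  }
  reason[blank(tab$junction_aa) & is.na(reason)] <- "missing junction_aa"
  reason[blank(tab$v_call) & is.na(reason)] <- "missing v_call"
  reason[blank(tab$j_call) & is.na(reason)] <- "missing j_call"
  keep <- is.na(reason)
  rejected <- tab[!keep, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$rejection_reason <- reason[!keep]
  rep <- as_repertoire(tab[keep, , drop = FALSE],
                       provenance = paste0("file:", path))
  if (nrow(rejected) > 0) {
    # align rejected rows to the repertoire's column set
    full <- as_repertoire(rejected[, setdiff(names(rejected),
                                             "rejection_reason"),
                                   drop = FALSE])$records
    full$rejection_reason <- rejected$rejection_reason
    rep$rejected <- full
  }
  validate_repertoire(rep)
}

#' Write an AIRR Rearrangement TSV
#'
#' Writes a [repertoire] as a tab-separated AIRR Rearrangement file with a
#' stable column order. Optional columns are emitted only when at least one
#' record carries a value; inferred clone labels are written to the standard
#' `clone_id` column when a partition is supplied.
#'
#' @param rep a [repertoire].
#' @param path output file path.
#' @param partition optional [clonal_partition]; its labels are written to
#'   `clone_id`.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(rep, path, partition = NULL) {
  validate_repertoire(rep)
  rec <- rep$records
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "clonal_partition"))
    rec$clone_id <- unname(partition$assignment[as.character(rec$sequence_id)])
  }
  cols <- .airr_core_cols
  for (col in .airr_opt_cols) {
    if (col %in% names(rec) && any(!is.na(rec[[col]]))) cols <- c(cols, col)
  }
  extra <- setdiff(names(rec), c(.airr_core_cols, .airr_opt_cols))
  out <- rec[, c(cols, extra), drop = FALSE]
  for (col in names(out)) {
    v <- out[[col]]
    v <- as.character(v)
    v[is.na(v)] <- ""
    out[[col]] <- v
  }
  ok <- tryCatch({
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Export repertoire sequences as FASTA
#'
#' Writes the `sequence` column keyed by `sequence_id`. Uses Biostrings when
#' available.
#'
#' @param rep a [repertoire].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(rep, path) {
  rec <- rep$records
  seqs <- as.character(rec$sequence)
  if (any(is.na(seqs))) stop("records without a sequence cannot be exported",
                             call. = FALSE)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- as.character(rec$sequence_id)
    Biostrings::writeXStringSet(x, filepath = path)
  } else {
    writeLines(paste0(">", rec$sequence_id, "\n", seqs), path)
  }
  invisible(path)
}

#' Reduce a V or J gene call to a single gene-level name
#'
#' Multi-assigned calls are comma-separated lists; the first listed call is
#' taken and any `*NN` allele suffix removed, giving the gene-level name used
#' for VJ partitioning.
#'
#' @param call character vector of gene calls (e.g. `"IGHV1-69*01"`,
#'   `"IGHV3-23*04,IGHV3-23D*01"`).
#' @return character vector of gene-level names.
#' @examples
#' strip_allele("IGHV1-69*01")                  # "IGHV1-69"
#' strip_allele("IGHV3-23*04,IGHV3-23D*01")     # "IGHV3-23"
#' @export
strip_allele <- function(call) {
  call <- as.character(call)
  if (any(is.na(call) | !nzchar(call))) {
    stop("empty gene call", call. = FALSE)
  }
  first <- sub(",.*$", "", call)
  sub("\\*[0-9A-Za-z]+$", "", first)
}
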