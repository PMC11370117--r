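#' @title Repertoire objects
#'
#' @description A `repertoire` is the package's central container: an ordered
#' collection of annotated BCR heavy-chain rearrangement records, one row per
#' sequence, together with the set of sample identifiers and free-text
#' provenance. Records live in a plain `data.frame` so that standard
#' data-manipulation tools apply directly.
#'
#' @details Recognised record columns:
#' \describe{
#'   \item{sequence_id}{unique identifier, one per record}
#'   \item{sample_id}{sample of origin}
#'   \item{sequence}{full nucleotide sequence over `{A,C,G,T,N}`}
#'   \item{v_call, j_call}{V/J gene assignments; allele suffixes (`*01`) and
#'     comma-separated multiple calls are retained verbatim and resolved at
#'     analysis time by [strip_allele()]}
#'   \item{junction, junction_aa}{junction nucleotides (CDR3 plus the two
#'     anchor codons, Cys104 and Phe/Trp118) and its translation}
#'   \item{v_mutation_count, v_alignment_length, j_mutation_count,
#'     j_alignment_length}{mutation counts and alignment lengths used for the
#'     mutation-load summary}
#'   \item{lc_v_call, lc_j_call}{optional paired light-chain V/J calls}
#'   \item{clone_id_true}{optional ground-truth clone label (simulated data)}
#' }
#' @name repertoire
NULL

# Column order used on output; optional columns appear only when populated.
.airr_core_cols <- c("sequence_id", "sample_id", "sequence", "v_call",
                     "j_call", "junction", "junction_aa")
.airr_opt_cols <- c("v_mutation_count", "v_alignment_length",
                    "j_mutation_count", "j_alignment_length",
                    "lc_v_call", "lc_j_call", "clone_id_true", "clone_id")

#' Construct a repertoire
#'
#' @param records data.frame of rearrangement records. Must contain at least
#'   `sequence_id`, `v_call`, `j_call`, `junction_aa`; missing optional
#'   columns are added as `NA`.
#' @param provenance free-text provenance string.
#' @param rejected data.frame of records excluded from analysis, with a
#'   `rejection_reason` column. Default: empty.
#' @return An object of class `repertoire`: a list with elements `records`
#'   (data.frame), `rejected` (data.frame) and `provenance` (character).
#' @examples
#' rep <- as_repertoire(data.frame(
#'   sequence_id = c("s1", "s2"), sample_id = "S1",
#'   sequence = c("TGTGCGAGATGG", "TGTGCGAAATGG"),
#'   v_call = "IGHV1-69*01", j_call = "IGHJ4",
#'   junction = c("TGTGCGAGATGG", "TGTGCGAAATGG"),
#'   junction_aa = c("CARW", "CAKW")))
#' n_records(rep)
#' @export
as_repertoire <- function(records, provenance = "", rejected = NULL) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("sequence_id", "v_call", "j_call", "junction_aa")
  miss <- setdiff(need, names(records))
  if (nrow(records) > 0 && length(miss) > 0) {
    stop("records are missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in c(.airr_core_cols, .airr_opt_cols)) {
    if (!col %in% names(records)) records[[col]] <- rep(NA, nrow(records))
  }
  if (anyDuplicated(records$sequence_id)) {
    dup <- unique(records$sequence_id[duplicated(records$sequence_id)])
    stop("duplicate sequence_id value(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(rejected)) {
    rejected <- records[0, , drop = FALSE]
    rejected$rejection_reason <- character(0)
  }
  structure(list(records = records, rejected = rejected,
                 provenance = provenance),
            class = "repertoire")
}

#' @rdname as_repertoire
#' @param x a `repertoire`.
#' @export
n_records <- function(x) nrow(x$records)

#' @rdname as_repertoire
#' @export
sample_ids <- function(x) unique(as.character(x$records$sample_id))

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %d records, %d sample(s), %d rejected\n",
              n_records(x), length(sample_ids(x)), nrow(x$rejected)))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Validate repertoire invariants
#'
#' Checks sequence-id uniqueness, junction/translation length consistency and
#' mutation-count bounds. Invoked by the writers; exported for direct use.
#'
#' @param rep a `repertoire`.
#' @return `rep`, invisibly; stops on violation.
#' @export
validate_repertoire <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  rec <- rep$records
  if (anyDuplicated(rec$sequence_id)) {
    stop("sequence_id values are not unique", call. = FALSE)
  }
  has_aa <- !is.na(rec$junction_aa) & nzchar(as.character(rec$junction_aa))
  has_nt <- !is.na(rec$junction) & nzchar(as.character(rec$junction))
  both <- has_aa & has_nt
  if (any(both)) {
    jl <- nchar(as.character(rec$junction[both]))
    al <- nchar(as.character(rec$junction_aa[both]))
    bad <- jl %% 3 == 0 & al != jl / 3
    if (any(bad)) {
      stop("junction_aa length inconsistent with junction length for: ",
           paste(utils::head(rec$sequence_id[both][bad], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  for (seg in c("v", "j")) {
    mc <- rec[[paste0(seg, "_mutation_count")]]
    al <- rec[[paste0(seg, "_alignment_length")]]
    ok <- is.na(mc) | is.na(al) | mc <= al
    if (!all(ok)) {
      stop(seg, "_mutation_count exceeds ", seg, "_alignment_length for: ",
           paste(utils::head(rec$sequence_id[!ok], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  lc_v <- !is.na(rec$lc_v_call)
  lc_j <- !is.na(rec$lc_j_call)
  if (any(lc_v != lc_j)) {
    stop("lc_v_call and lc_j_call must be both present or both absent",
         call. = FALSE)
  }
  invisible(rep)
}

#' Records whose junction translates cleanly
#'
#' AA-based approaches operate only on records whose junction length is a
#' multiple of three and whose `junction_aa` is present; NT-based approaches
#' keep all records with a junction.
#'
#' @param rep a `repertoire`.
#' @return logical vector over records, TRUE where the amino-acid junction is
#'   usable.
#' @keywords internal
translatable <- function(rep) {
  rec <- rep$records
  aa <- as.character(rec$junction_aa)
  nt <- as.character(rec$junction)
  ok <- !is.na(aa) & nzchar(aa)
  has_nt <- !is.na(nt) & nzchar(nt)
  ok & (!has_nt | nchar(nt) %% 3 == 0)
}
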