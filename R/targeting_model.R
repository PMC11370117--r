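#' 5-mer somatic-hypermutation targeting model
#'
#' A targeting model assigns every DNA 5-mer a relative mutability for its
#' central base and a substitution distribution over the three alternative
#' bases. The default is a flat model with classic AID hotspots (WRC/GYW,
#' where W = A/T, R = A/G, Y = C/T) elevated and SYC/GRS coldspots
#' (S = C/G) suppressed — a configurable stand-in for published human
#' heavy-chain 5-mer targeting tables, which can be loaded from TSV with
#' [load_targeting_model()].
#'
#' @param hotspot_fold relative mutability of WRC/GYW hotspot contexts
#'   (default 5).
#' @param coldspot_fold relative mutability of SYC/GRS coldspot contexts
#'   (default 0.3).
#' @return an object of class `targeting_model`: a list with `mutability`
#'   (named numeric over the 1024 5-mers) and `substitution` (1024 x 4
#'   matrix of substitution probabilities for the central base; rows sum
#'   to 1, the central base's own column is 0).
#' @examples
#' m <- targeting_model()
#' m$mutability[["TACGT"]]  # WRC hotspot (central C preceded by A, T)
#' @export
targeting_model <- function(hotspot_fold = 5, coldspot_fold = 0.3) {
  stopifnot(hotspot_fold >= 0, coldspot_fold >= 0)
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b1 = bases, b2 = bases, b3 = bases, b4 = bases,
                      b5 = bases, stringsAsFactors = FALSE)
  kmers <- do.call(paste0, grid)
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T"); S <- c("C", "G")
  # center = b3; WRC reads positions (b1, b2, b3); GYW reads (b3, b4, b5)
  hot <- (grid$b3 == "C" & grid$b2 %in% R & grid$b1 %in% W) |
         (grid$b3 == "G" & grid$b4 %in% Y & grid$b5 %in% W)
  cold <- (!hot) & ((grid$b3 == "C" & grid$b2 %in% Y & grid$b1 %in% S) |
                    (grid$b3 == "G" & grid$b4 %in% R & grid$b5 %in% S))
  mutability <- rep(1, length(kmers))
  mutability[hot] <- hotspot_fold
  mutability[cold] <- coldspot_fold
  names(mutability) <- kmers
  substitution <- matrix(1 / 3, nrow = length(kmers), ncol = 4,
                         dimnames = list(kmers, bases))
  for (b in bases) substitution[grid$b3 == b, b] <- 0
  substitution <- substitution / rowSums(substitution)
  structure(list(mutability = mutability, substitution = substitution),
            class = "targeting_model")
}

#' Load a targeting model from TSV tables
#'
#' @param mutability_path 2-column TSV (`fivemer`, `mutability`), one row
#'   per 5-mer; unlisted 5-mers default to mutability 1.
#' @param substitution_path optional TSV with columns `fivemer`, `A`, `C`,
#'   `G`, `T` giving substitution probabilities for the central base; rows
#'   are renormalised. When absent, substitution is uniform over the three
#'   alternative bases.
#' @return a `targeting_model`.
#' @export
load_targeting_model <- function(mutability_path, substitution_path = NULL) {
  base <- targeting_model(hotspot_fold = 1, coldspot_fold = 1)
  tab <- utils::read.delim(mutability_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("fivemer", "mutability") %in% names(tab))) {
    stop("mutability table needs columns 'fivemer' and 'mutability'",
         call. = FALSE)
  }
  if (any(tab$mutability < 0)) stop("mutability must be non-negative",
                                    call. = FALSE)
  known <- tab$fivemer %in% names(base$mutability)
  base$mutability[tab$fivemer[known]] <- tab$mutability[known]
  if (!is.null(substitution_path)) {
    sub <- utils::read.delim(substitution_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    need <- c("fivemer", "A", "C", "G", "T")
    if (!all(need %in% names(sub))) {
      stop("substitution table needs columns fivemer, A, C, G, T",
           call. = FALSE)
    }
    m <- as.matrix(sub[, c("A", "C", "G", "T")])
    rownames(m) <- sub$fivemer
    keep <- rownames(m) %in% rownames(base$substitution)
    m <- m[keep, , drop = FALSE]
    # central base cannot substitute to itself
    center <- substr(rownames(m), 3, 3)
    m[cbind(seq_len(nrow(m)), match(center, c("A", "C", "G", "T")))] <- 0
    m <- m / rowSums(m)
    base$substitution[rownames(m), ] <- m
  }
  base
}

#' @export
print.targeting_model <- function(x, ...) {
  cat(sprintf("<targeting_model> %d 5-mers; mutability range [%.3g, %.3g]\n",
              length(x$mutability), min(x$mutability), max(x$mutability)))
  invisible(x)
}
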