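#' Simulation configuration
#'
#' Bundles every knob of the repertoire generator. Defaults describe a
#' mid-depth bulk heavy-chain sample: a few hundred clones with a
#' heavy-tailed size distribution, a sizeable singleton compartment, and a
#' light somatic-hypermutation load.
#'
#' @param seed integer; master seed from which all named random streams are
#'   derived.
#' @param n_clones number of clonal families to generate.
#' @param depth target total number of records; allocated across clones
#'   proportionally to their drawn size weights (clones forced to singleton
#'   status always contribute exactly one record, so the realised total can
#'   differ slightly from `depth`).
#' @param clone_size_distribution list describing the clone-size weight
#'   distribution: `list(type = "powerlaw", exponent = 2.5)`,
#'   `list(type = "geometric", p = 0.3)` or `list(type = "fixed", k = 10)`.
#' @param singleton_fraction probability that a clone is forced to size 1.
#' @param n_v_segments,n_j_segments size of the synthetic germline catalogue.
#' @param v_segment_length,j_segment_length germline segment lengths (nt).
#'   The V segment ends with the Cys104 anchor codon and the J segment
#'   starts with the Trp118 anchor codon.
#' @param junction_insertion_mean mean of the Poisson junctional-insertion
#'   length (nt); draws are padded up to a multiple of 3 so the junction
#'   stays in frame.
#' @param mutation_rate_per_site expected per-site mutation probability on
#'   each lineage-tree edge (before 5-mer mutability weighting).
#' @param max_tree_depth maximum depth of a lineage tree (root = 0).
#' @param targeting 5-mer [targeting_model()] used for SHM.
#' @param emit_light_chain if TRUE, each clone is assigned one light-chain
#'   V/J pair emitted on all members.
#' @param lc_discordance_rate per-record probability that the clone's
#'   light-chain pair is replaced by a random different one.
#' @param n_samples number of samples the repertoire is split into.
#' @param per_sample_mixing optional `n_clones x n_samples` matrix of
#'   per-clone sample proportions (rows sum to 1). Default: each clone is
#'   assigned wholly to one sample, round-robin.
#' @param collision_rate probability that a clone reuses an already-taken
#'   (V gene, J gene, junction length) triple; 0 keeps all clone ancestors
#'   in distinct VJ-partition groups so that perfect recovery is possible.
#' @param germline_seed optional separate seed for the germline catalogue.
#'   Repertoires simulated with the same `germline_seed` share one germline
#'   gene set — as different individuals of one species do — which matters
#'   when one repertoire serves as another's negation reference.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1,
                              n_clones = 200,
                              depth = 1000,
                              clone_size_distribution =
                                list(type = "powerlaw", exponent = 2.5),
                              singleton_fraction = 0.4,
                              n_v_segments = 20,
                              n_j_segments = 6,
                              v_segment_length = 150,
                              j_segment_length = 42,
                              junction_insertion_mean = 36,
                              mutation_rate_per_site = 0.005,
                              max_tree_depth = 10,
                              targeting = targeting_model(),
                              emit_light_chain = FALSE,
                              lc_discordance_rate = 0,
                              n_samples = 1,
                              per_sample_mixing = NULL,
                              collision_rate = 0,
                              germline_seed = NULL) {
  stopifnot(n_clones >= 1, depth >= n_clones,
            singleton_fraction >= 0, singleton_fraction <= 1,
            n_v_segments >= 1, n_j_segments >= 1,
            v_segment_length >= 12, j_segment_length >= 12,
            junction_insertion_mean >= 0,
            mutation_rate_per_site >= 0, mutation_rate_per_site <= 1,
            max_tree_depth >= 1, n_samples >= 1,
            lc_discordance_rate >= 0, lc_discordance_rate <= 1,
            collision_rate >= 0, collision_rate <= 1)
  if (!is.list(clone_size_distribution) ||
      !clone_size_distribution$type %in% c("powerlaw", "geometric", "fixed")) {
    stop("clone_size_distribution$type must be powerlaw, geometric or fixed",
         call. = FALSE)
  }
  if (!is.null(per_sample_mixing)) {
    per_sample_mixing <- as.matrix(per_sample_mixing)
    if (nrow(per_sample_mixing) != n_clones ||
        ncol(per_sample_mixing) != n_samples) {
      stop("per_sample_mixing must be n_clones x n_samples", call. = FALSE)
    }
    if (any(per_sample_mixing < 0) ||
        any(abs(rowSums(per_sample_mixing) - 1) > 1e-8)) {
      stop("per_sample_mixing rows must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  structure(list(seed = seed, n_clones = n_clones, depth = depth,
                 clone_size_distribution = clone_size_distribution,
                 singleton_fraction = singleton_fraction,
                 n_v_segments = n_v_segments, n_j_segments = n_j_segments,
                 v_segment_length = v_segment_length,
                 j_segment_length = j_segment_length,
                 junction_insertion_mean = junction_insertion_mean,
                 mutation_rate_per_site = mutation_rate_per_site,
                 max_tree_depth = max_tree_depth, targeting = targeting,
                 emit_light_chain = emit_light_chain,
                 lc_discordance_rate = lc_discordance_rate,
                 n_samples = n_samples,
                 per_sample_mixing = per_sample_mixing,
                 collision_rate = collision_rate,
                 germline_seed = germline_seed),
            class = "simulation_config")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.hamming_chr <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Generate a synthetic germline segment catalogue
#'
#' Produces named V and J nucleotide segments standing in for a germline
#' database. Every V segment ends with the Cys anchor codon `TGT` and every
#' J segment starts with the Trp anchor codon `TGG`; any two segments of the
#' same type differ at 3 or more positions so that gene-level VJ
#' partitioning of the simulated data is unambiguous.
#'
#' @param config a [simulation_config()].
#' @param seed optional seed override (defaults to `config$seed`).
#' @return list with data.frames `v` and `j` (`name`, `sequence`).
#' @export
generate_germline_set <- function(config, seed = config$seed) {
  gen_segments <- function(n, len, prefix, anchor, anchor_at_end) {
    if (len < 12) stop("segment length too short to enforce divergence",
                       call. = FALSE)
    seqs <- character(0)
    for (i in seq_len(n)) {
      repeat {
        body <- .rand_dna(len - 3)
        s <- if (anchor_at_end) paste0(body, anchor) else paste0(anchor, body)
        if (all(vapply(seqs, function(p) .hamming_chr(p, s) >= 3, logical(1)))) {
          break
        }
      }
      seqs <- c(seqs, s)
    }
    data.frame(name = sprintf("%s-%d", prefix, seq_len(n)),
               sequence = seqs, stringsAsFactors = FALSE)
  }
  with_stream(seed, "germline", expr = {
    list(v = gen_segments(config$n_v_segments, config$v_segment_length,
                          "SIMV", "TGT", anchor_at_end = TRUE),
         j = gen_segments(config$n_j_segments, config$j_segment_length,
                          "SIMJ", "TGG", anchor_at_end = FALSE))
  })
}

.stop_codons <- c("TAA", "TAG", "TGA")

# Random in-frame junction insertion free of stop codons.
.rand_insertion <- function(len) {
  if (len == 0) return("")
  stopifnot(len %% 3 == 0)
  codons <- character(len / 3)
  for (i in seq_along(codons)) {
    repeat {
      cd <- .rand_dna(3)
      if (!cd %in% .stop_codons) break
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

#' Simulate a naive (unmutated) VDJ rearrangement
#'
#' Draws a V and J segment according to the usage frequencies, inserts a
#' junctional segment of Poisson-distributed length (padded to a multiple
#' of 3, stop-codon free) between them, and records the junction
#' coordinates: the junction comprises the V segment's final (Cys) codon,
#' the insertion, and the J segment's first (Trp) codon.
#'
#' @param catalogue output of [generate_germline_set()].
#' @param config a [simulation_config()].
#' @param seed seed for this draw.
#' @param v_idx,j_idx,insertion_length optional overrides for the segment
#'   choices and insertion length (used to steer clone ancestors into
#'   distinct VJ groups).
#' @return list with `sequence`, `v_call`, `j_call`, `junction`,
#'   `junction_aa`, `junction_start`, `junction_length`, `v_idx`, `j_idx`.
#' @export
simulate_naive_rearrangement <- function(catalogue, config, seed,
                                         v_idx = NULL, j_idx = NULL,
                                         insertion_length = NULL) {
  with_stream(seed, "naive", expr = {
    if (is.null(v_idx)) v_idx <- sample.int(nrow(catalogue$v), 1)
    if (is.null(j_idx)) j_idx <- sample.int(nrow(catalogue$j), 1)
    if (is.null(insertion_length)) {
      insertion_length <- stats::rpois(1, config$junction_insertion_mean)
    }
    # pad up so the junction stays a multiple of 3
    insertion_length <- insertion_length +
      (3 - insertion_length %% 3) %% 3
    vseq <- catalogue$v$sequence[v_idx]
    jseq <- catalogue$j$sequence[j_idx]
    ins <- .rand_insertion(insertion_length)
    sequence <- paste0(vseq, ins, jseq)
    junction_start <- nchar(vseq) - 2
    junction_length <- 3 + insertion_length + 3
    junction <- substr(sequence, junction_start,
                       junction_start + junction_length - 1)
    list(sequence = sequence,
         v_call = paste0(catalogue$v$name[v_idx], "*01"),
         j_call = paste0(catalogue$j$name[j_idx], "*01"),
         junction = junction,
         junction_aa = translate_nt(junction),
         junction_start = junction_start,
         junction_length = junction_length,
         v_idx = v_idx, j_idx = j_idx)
  })
}

#' Translate a nucleotide string to amino acids
#'
#' @param nt nucleotide string; length must be a multiple of 3.
#' @return amino-acid string (`*` for stop codons).
#' @export
translate_nt <- function(nt) {
  stopifnot(nchar(nt) %% 3 == 0)
  if (nchar(nt) == 0) return("")
  paste(seqinr::translate(seqinr::s2c(nt)), collapse = "")
}

#' Sample a random lineage-tree topology
#'
#' Random recursive tree: node i attaches uniformly to one of the earlier
#' nodes whose depth is below `max_depth`. Node 1 is the root (the
#' unmutated ancestor placeholder).
#'
#' @param n_nodes number of subclone nodes (>= 1).
#' @param seed seed for the draw.
#' @param max_depth maximum allowed depth (root = 0).
#' @return a `lineage_tree`: list with `n_nodes`, `parent` (integer vector,
#'   `NA` for the root) and `depth`.
#' @export
sample_tree_topology <- function(n_nodes, seed, max_depth = 10) {
  if (n_nodes < 1) stop("n_nodes must be >= 1", call. = FALSE)
  with_stream(seed, "tree", expr = {
    parent <- rep(NA_integer_, n_nodes)
    depth <- integer(n_nodes)
    if (n_nodes > 1) {
      for (i in 2:n_nodes) {
        eligible <- which(depth[seq_len(i - 1)] < max_depth)
        p <- if (length(eligible) == 1) eligible else sample(eligible, 1)
        parent[i] <- p
        depth[i] <- depth[p] + 1
      }
    }
    structure(list(n_nodes = n_nodes, parent = parent, depth = depth),
              class = "lineage_tree")
  })
}

# Vector of 5-mer contexts for every position of a sequence (edge positions
# padded with N, which falls back to mutability 1).
.fivemer_contexts <- function(chars) {
  n <- length(chars)
  padded <- c("N", "N", chars, "N", "N")
  paste0(padded[seq_len(n)], padded[seq_len(n) + 1], padded[seq_len(n) + 2],
         padded[seq_len(n) + 3], padded[seq_len(n) + 4])
}

# One round of context-dependent point mutation of a parent sequence.
.mutate_once <- function(chars, model, rate) {
  n <- length(chars)
  ctx <- .fivemer_contexts(chars)
  mut <- model$mutability[ctx]
  mut[is.na(mut)] <- 1
  # normalise so the mean per-site probability equals `rate`
  p <- rate * mut / mean(mut)
  p <- pmin(p, 1)
  hit <- which(stats::runif(n) < p)
  for (i in hit) {
    probs <- if (ctx[i] %in% rownames(model$substitution)) {
      model$substitution[ctx[i], ]
    } else {
      probs0 <- stats::setNames(rep(1 / 3, 4), c("A", "C", "G", "T"))
      probs0[chars[i]] <- 0
      probs0 / sum(probs0)
    }
    chars[i] <- sample(c("A", "C", "G", "T"), 1, prob = probs)
  }
  chars
}

#' Impose somatic hypermutation along a lineage tree
#'
#' The root keeps the ancestor sequence unchanged; every child derives from
#' its parent by per-site substitution with probability
#' `rate x` (5-mer mutability, normalised to mean 1). Substitution only:
#' sequence length is preserved.
#'
#' @param ancestor nucleotide string (the unmutated root).
#' @param tree a [sample_tree_topology()] result.
#' @param model a [targeting_model()].
#' @param rate expected per-site mutation probability per edge, in `[0,1]`.
#' @param seed seed for the draws.
#' @return character vector of node sequences (index = node).
#' @export
mutate_lineage <- function(ancestor, tree, model, rate, seed) {
  stopifnot(nzchar(ancestor), rate >= 0, rate <= 1)
  seqs <- vector("list", tree$n_nodes)
  seqs[[1]] <- strsplit(ancestor, "")[[1]]
  if (tree$n_nodes > 1 && rate > 0) {
    for (i in 2:tree$n_nodes) {
      seqs[[i]] <- with_stream(seed, "edge", i, expr = {
        .mutate_once(seqs[[tree$parent[i]]], model, rate)
      })
    }
  } else if (tree$n_nodes > 1) {
    for (i in 2:tree$n_nodes) seqs[[i]] <- seqs[[1]]
  }
  vapply(seqs, paste, character(1), collapse = "")
}

# Largest-remainder allocation of `total` items over non-negative weights;
# entries with positive weight receive at least `minimum` when possible.
.allocate <- function(total, weights, minimum = 0) {
  k <- length(weights)
  if (k == 0) return(integer(0))
  pos <- weights > 0
  alloc <- integer(k)
  if (minimum > 0) {
    alloc[pos] <- min(minimum, floor(total / max(1, sum(pos))))
  }
  rem <- total - sum(alloc)
  if (rem > 0 && any(pos)) {
    w <- weights / sum(weights)
    extra <- floor(w * rem)
    alloc <- alloc + extra
    left <- rem - sum(extra)
    if (left > 0) {
      frac <- w * rem - extra
      frac[!pos] <- -Inf  # remainder never goes to zero-weight entries
      take <- order(-frac, seq_len(k))[seq_len(left)]
      alloc[take] <- alloc[take] + 1L
    }
  }
  alloc
}

.draw_size_weights <- function(n, dist) {
  switch(dist$type,
         powerlaw = {
           # discrete power-law via inverse-CDF on a Pareto tail
           u <- stats::runif(n)
           floor((1 - u)^(-1 / (dist$exponent - 1)))
         },
         geometric = 1 + stats::rgeom(n, dist$p),
         fixed = rep(dist$k, n))
}

#' Simulate an annotated repertoire with clonal ground truth
#'
#' Runs the full generative model: a synthetic germline catalogue, one naive
#' VDJ rearrangement per clone (distinct V/J/junction-length triples unless
#' `collision_rate > 0`), a random lineage tree per clone, 5-mer
#' context-dependent somatic hypermutation along the tree, and per-node copy
#' numbers. Every record carries its true clone label in `clone_id_true`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `repertoire` (a [repertoire]) and `truth`
#'   (the ground-truth [clonal_partition]).
#' @examples
#' sim <- simulate_repertoire(simulation_config(seed = 7, n_clones = 10,
#'                                              depth = 50))
#' table(sim$repertoire$records$clone_id_true)
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  catalogue <- generate_germline_set(
    config, seed = if (!is.null(config$germline_seed))
      config$germline_seed else config$seed)
  n <- config$n_clones

  # --- clone ancestors with controllable VJ/junction-length collisions ----
  taken <- character(0)
  taken_junctions <- character(0)
  ancestors <- vector("list", n)
  for (i in seq_len(n)) {
    cseed <- stream_seed(config$seed, "clone", i)
    anc <- NULL
    for (attempt in 1:200) {
      anc <- simulate_naive_rearrangement(
        catalogue, config, stream_seed(cseed, "naive", attempt))
      key <- paste(anc$v_idx, anc$j_idx, anc$junction_length, sep = "|")
      allow_collision <- with_stream(cseed, "collision", expr = {
        stats::runif(1) < config$collision_rate
      })
      if ((allow_collision || !key %in% taken) &&
          !anc$junction %in% taken_junctions) {
        taken <- c(taken, key)
        taken_junctions <- c(taken_junctions, anc$junction)
        break
      }
      anc <- NULL
    }
    if (is.null(anc)) {
      stop("could not draw a distinct ancestor for clone ", i,
           "; increase segment counts or junction length variability",
           call. = FALSE)
    }
    ancestors[[i]] <- anc
  }

  # --- clone sizes --------------------------------------------------------
  singleton <- vapply(seq_len(n), function(i) {
    with_stream(config$seed, "clone", i, "singleton", expr = {
      stats::runif(1) < config$singleton_fraction
    })
  }, logical(1))
  weights <- vapply(seq_len(n), function(i) {
    with_stream(config$seed, "clone", i, "size", expr = {
      as.numeric(.draw_size_weights(1, config$clone_size_distribution))
    })
  }, numeric(1))
  sizes <- integer(n)
  sizes[singleton] <- 1L
  n_rest <- sum(!singleton)
  if (n_rest > 0) {
    budget <- max(config$depth - sum(singleton), 2 * n_rest)
    sizes[!singleton] <- pmax(2L, .allocate(budget, weights[!singleton],
                                            minimum = 2))
  }

  # --- light-chain catalogue ---------------------------------------------
  lc_pairs <- NULL
  if (config$emit_light_chain) {
    lc_pairs <- expand.grid(v = sprintf("SIMLCV-%d", 1:8),
                            j = sprintf("SIMLCJ-%d", 1:4),
                            stringsAsFactors = FALSE)
  }

  # --- expand clones ------------------------------------------------------
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    anc <- ancestors[[i]]
    s <- sizes[i]
    cseed <- stream_seed(config$seed, "clone", i)
    m <- if (s == 1) 1L else with_stream(cseed, "nodes", expr = {
      max(1L, min(s, 1L + stats::rbinom(1, s - 1L, 0.6)))
    })
    tree <- sample_tree_topology(m, stream_seed(cseed, "topology"),
                                 max_depth = config$max_tree_depth)
    node_seqs <- mutate_lineage(anc$sequence, tree, config$targeting,
                                config$mutation_rate_per_site,
                                stream_seed(cseed, "shm"))
    # geometric copy-number weights over nodes, summing to clone size
    copy <- with_stream(cseed, "copies", expr = {
      w <- 1 + stats::rgeom(m, 0.5)
      .allocate(s, w, minimum = 1)
    })
    # drop unexpressed nodes (allocation can starve some when s ~ m)
    keep <- which(copy > 0)

    jn_start <- anc$junction_start
    jn_len <- anc$junction_length
    v_len <- nchar(catalogue$v$sequence[anc$v_idx])
    j_len <- nchar(catalogue$j$sequence[anc$j_idx])
    v_germ <- strsplit(catalogue$v$sequence[anc$v_idx], "")[[1]]
    j_germ <- strsplit(catalogue$j$sequence[anc$j_idx], "")[[1]]

    clone_rows <- lapply(keep, function(node) {
      seq_nt <- node_seqs[node]
      chars <- strsplit(seq_nt, "")[[1]]
      v_mut <- sum(chars[seq_len(v_len)] != v_germ)
      j_mut <- sum(chars[(length(chars) - j_len + 1):length(chars)] != j_germ)
      junction <- substr(seq_nt, jn_start, jn_start + jn_len - 1)
      data.frame(node = node,
                 sequence = seq_nt,
                 junction = junction,
                 junction_aa = translate_nt(junction),
                 v_mutation_count = v_mut,
                 j_mutation_count = j_mut,
                 copies = copy[node],
                 stringsAsFactors = FALSE)
    })
    clone_df <- do.call(rbind, clone_rows)
    clone_df <- clone_df[rep(seq_len(nrow(clone_df)), clone_df$copies), ,
                         drop = FALSE]
    clone_df$copies <- NULL
    clone_df$clone_id_true <- sprintf("C%04d", i)
    clone_df$v_call <- anc$v_call
    clone_df$j_call <- anc$j_call
    clone_df$v_alignment_length <- v_len
    clone_df$j_alignment_length <- j_len

    # sample assignment
    mix <- if (!is.null(config$per_sample_mixing)) {
      config$per_sample_mixing[i, ]
    } else {
      m0 <- rep(0, config$n_samples)
      m0[(i - 1) %% config$n_samples + 1] <- 1
      m0
    }
    counts <- .allocate(nrow(clone_df), mix,
                        minimum = if (sum(mix > 0) <= nrow(clone_df)) 1 else 0)
    clone_df$sample_id <- rep(sprintf("S%d", seq_len(config$n_samples)),
                              counts)

    # light chain
    if (config$emit_light_chain) {
      pair <- with_stream(cseed, "lc", expr = {
        lc_pairs[sample.int(nrow(lc_pairs), 1), ]
      })
      clone_df$lc_v_call <- pair$v
      clone_df$lc_j_call <- pair$j
      if (config$lc_discordance_rate > 0) {
        flip <- with_stream(cseed, "lc_flip", expr = {
          stats::runif(nrow(clone_df)) < config$lc_discordance_rate
        })
        if (any(flip)) {
          repl <- with_stream(cseed, "lc_repl", expr = {
            lc_pairs[sample.int(nrow(lc_pairs), sum(flip), replace = TRUE), ,
                     drop = FALSE]
          })
          clone_df$lc_v_call[flip] <- repl$v
          clone_df$lc_j_call[flip] <- repl$j
        }
      }
    }
    clone_df$sequence_id <- sprintf("C%04d_N%02d_R%03d", i,
                                    clone_df$node, seq_len(nrow(clone_df)))
    clone_df$node <- NULL
    rows[[i]] <- clone_df
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  rep <- as_repertoire(records,
                       provenance = sprintf("simulate_repertoire(seed=%d)",
                                            config$seed))
  truth <- new_clonal_partition(
    "TRUE",
    stats::setNames(records$clone_id_true, records$sequence_id),
    params = list(seed = config$seed, n_clones = config$n_clones))
  list(repertoire = rep, truth = truth)
}
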