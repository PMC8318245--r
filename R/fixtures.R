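# Seeded synthetic protein-family generator. Families emulate the one
# structural assumption the profile method rests on: homologs conserve
# secondary structure better than sequence. A query is drawn from a
# segment grammar with per-SSE-class amino-acid emissions; homologs are
# substitution mutants at a requested identity whose SSE is preserved up
# to segment-end jitter.

# default per-class amino-acid emission tables: mild, realistic
# preferences (helix formers A/L/E/M/Q, strand formers V/I/Y/F/T/W, coil
# formers G/P/S/N/D) so sequence carries weak SSE signal while profiles
# carry strong signal.
.default_emissions <- local({
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  base <- stats::setNames(rep(1, 20), aas)
  h <- base; h[c("A", "L", "E", "M", "Q", "K", "R")] <- 3
  e <- base; e[c("V", "I", "Y", "F", "T", "W", "L")] <- 3
  c0 <- base; c0[c("G", "P", "S", "N", "D")] <- 3
  list(H = h / sum(h), E = e / sum(e), C = c0 / sum(c0))
})

#' Synthetic family parameters
#'
#' @param n_targets Number of homologs generated per query.
#' @param length_range Two-integer range of query lengths (residues).
#' @param segment_length_ranges Named list of two-integer ranges per
#'   three-state class (`H`, `E`, `C`): lengths of sampled segments.
#' @param transition Named list of per-class transition weight vectors for
#'   the segment-type grammar (rows `H`, `E`, `C`; self-transitions are
#'   zeroed so consecutive segments differ).
#' @param emissions Named list of 20-vector amino-acid frequencies per
#'   three-state class; defaults encode mild helix/strand/coil residue
#'   preferences.
#' @param identity_range Two-fraction range; each homolog's target
#'   sequence identity with the query is drawn uniformly from it.
#' @param sse_jitter_prob Probability that a homolog segment boundary is
#'   jittered (grown/shrunk by up to 2 residues); segment structure, not
#'   per-residue labels, is perturbed.
#' @param alphabet Output alphabet, `"q3"` or `"dssp8"`; eight-state
#'   output refines H segments into G/H/I and E into E/B, C into C/S/T at
#'   segment ends, so reductions recover the three-state truth.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A list of class `family_params`.
#' @export
family_params <- function(n_targets = 8L, length_range = c(60L, 100L),
                          segment_length_ranges = list(H = c(4L, 12L),
                                                       E = c(3L, 8L),
                                                       C = c(2L, 6L)),
                          transition = list(H = c(H = 0, E = 0.4, C = 0.6),
                                            E = c(H = 0.4, E = 0, C = 0.6),
                                            C = c(H = 0.55, E = 0.45, C = 0)),
                          emissions = .default_emissions,
                          identity_range = c(0.35, 0.8),
                          sse_jitter_prob = 0.1,
                          alphabet = "q3",
                          seed = 1L) {
  stopifnot(n_targets >= 1, length(length_range) == 2,
            length_range[1] >= 10, length_range[2] >= length_range[1],
            all(identity_range >= 0), all(identity_range <= 1),
            identity_range[1] <= identity_range[2],
            sse_jitter_prob >= 0, sse_jitter_prob <= 1)
  for (em in emissions)
    if (abs(sum(em) - 1) > 1e-6)
      stop("emission vectors must sum to 1", call. = FALSE)
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  if (!alphabet$name %in% c("q3", "dssp8"))
    stop("fixture alphabet must be 'q3' or 'dssp8'", call. = FALSE)
  structure(list(n_targets = as.integer(n_targets),
                 length_range = as.integer(length_range),
                 segment_length_ranges = segment_length_ranges,
                 transition = transition, emissions = emissions,
                 identity_range = identity_range,
                 sse_jitter_prob = sse_jitter_prob,
                 alphabet = alphabet, seed = as.integer(seed)),
            class = "family_params")
}

.sample_sse3 <- function(params) {
  n <- sample(seq(params$length_range[1], params$length_range[2]), 1L)
  classes <- c("H", "E", "C")
  cur <- sample(classes, 1L, prob = c(0.35, 0.25, 0.4))
  out <- character(0)
  while (length(out) < n) {
    rng <- params$segment_length_ranges[[cur]]
    len <- sample(seq(rng[1], rng[2]), 1L)
    out <- c(out, rep(cur, len))
    w <- params$transition[[cur]][classes]
    cur <- sample(classes, 1L, prob = w)
  }
  out[seq_len(n)]
}

.emit_sequence <- function(sse3, params) {
  aas <- names(params$emissions[[1]])
  vapply(sse3, function(cl)
    sample(aas, 1L, prob = params$emissions[[cl]]), character(1),
    USE.NAMES = FALSE)
}

# Refine a three-state segment string into eight states: helix segments
# get G/I caps on long helices, strand segments keep E with occasional B
# singletons, coil segments get T/S at segment ends.
.refine_to_dssp8 <- function(sse3) {
  segs <- rle(sse3)
  out <- character(0)
  for (i in seq_along(segs$values)) {
    len <- segs$lengths[i]
    cl <- segs$values[i]
    seg <- rep(cl, len)
    if (cl == "H" && len >= 6) {
      seg[1] <- "G"
      if (len >= 10) seg[len] <- "I"
    } else if (cl == "E" && len == 1) {
      seg[1] <- "B"
    } else if (cl == "C" && len >= 3) {
      seg[1] <- "T"
      if (len >= 4) seg[len] <- "S"
    }
    out <- c(out, seg)
  }
  out
}

# Jitter homolog SSE at segment ends: each boundary shifts by up to 2
# residues with probability sse_jitter_prob, preserving segment structure.
.jitter_sse <- function(sse3, prob) {
  segs <- rle(sse3)
  if (length(segs$values) < 2L || prob == 0) return(sse3)
  for (b in seq_len(length(segs$values) - 1L)) {
    if (stats::runif(1) < prob) {
      shift <- sample(c(-2L, -1L, 1L, 2L), 1L)
      left <- segs$lengths[b] + shift
      right <- segs$lengths[b + 1L] - shift
      if (left >= 1L && right >= 1L) {
        segs$lengths[b] <- left
        segs$lengths[b + 1L] <- right
      }
    }
  }
  inverse.rle(segs)
}

#' Generate one synthetic protein family
#'
#' Samples a query (SSE segment string from the grammar, amino acids from
#' per-class emissions), then derives each homolog by substituting random
#' positions until the requested identity is reached; at substituted
#' positions the new residue is drawn from the emission table of the
#' residue's SSE class, so secondary structure stays encoded. Homolog SSE
#' equals the query SSE up to segment-end jitter; homologs are full-length
#' (gapless) mutants, so the true alignments are trivial.
#'
#' @param params A [family_params()].
#' @param query_id,target_prefix Identifiers for the generated records.
#' @return List with `query` (list `id`, `seq`, `sse`), `targets` (named
#'   character vector of sequences), `target_sse` (named character vector),
#'   and `alignments` (the true gapless alignment table, columns as in
#'   [search_homologs()] output minus `score`).
#' @export
generate_family <- function(params = family_params(), query_id = "q1",
                            target_prefix = paste0(query_id, "_t")) {
  set.seed(params$seed)
  sse3 <- .sample_sse3(params)
  qseq <- .emit_sequence(sse3, params)
  n <- length(sse3)
  targets <- character(params$n_targets)
  target_sse <- character(params$n_targets)
  ids <- paste0(target_prefix, seq_len(params$n_targets))
  for (t in seq_len(params$n_targets)) {
    ident <- stats::runif(1, params$identity_range[1],
                          params$identity_range[2])
    n_mut <- round((1 - ident) * n)
    mut_pos <- if (n_mut > 0) sample.int(n, n_mut) else integer(0)
    hseq <- qseq
    for (p in mut_pos) {
      repeat {
        new <- sample(names(params$emissions[[1]]), 1L,
                      prob = params$emissions[[sse3[p]]])
        if (new != qseq[p]) break
      }
      hseq[p] <- new
    }
    hsse3 <- .jitter_sse(sse3, params$sse_jitter_prob)
    targets[t] <- paste(hseq, collapse = "")
    target_sse[t] <- paste(
      if (params$alphabet$name == "dssp8") .refine_to_dssp8(hsse3)
      else hsse3, collapse = "")
  }
  qsse <- paste(if (params$alphabet$name == "dssp8") .refine_to_dssp8(sse3)
                else sse3, collapse = "")
  qstr <- paste(qseq, collapse = "")
  aln <- data.frame(
    query_id = query_id, hit_id = ids, query_aln = qstr,
    hit_aln = targets,
    identity = vapply(targets, function(h) alignment_identity(qstr, h),
                      numeric(1), USE.NAMES = FALSE),
    q_start = 1L, h_start = 1L, stringsAsFactors = FALSE)
  list(query = list(id = query_id, seq = qstr, sse = qsse),
       targets = stats::setNames(targets, ids),
       target_sse = stats::setNames(target_sse, ids),
       alignments = aln)
}

# Coverage-corrected cross-set identity: matched columns of the best local
# alignment divided by the shorter sequence length (the convention of
# sequence non-redundancy pipelines, where a short high-identity patch in
# otherwise unrelated proteins does not count as homology).
cross_set_identity <- function(query, target, sp) {
  hits <- search_homologs(query, target, sp)
  if (nrow(hits) == 0L) return(0)
  max(vapply(seq_len(nrow(hits)), function(i) {
    q <- strsplit(hits$query_aln[i], "")[[1]]
    h <- strsplit(hits$hit_aln[i], "")[[1]]
    matches <- sum(q == h & q != "-")
    matches / min(nchar(query), nchar(target))
  }, numeric(1)))
}

#' Generate a train/test benchmark of synthetic families
#'
#' Generates `n_queries` independent families, splits the queries into
#' disjoint training and test sets, and pools every family's homologs
#' (with their SSE annotations) into a shared target library. Cross-set
#' query identities (matched columns of the best local alignment over the
#' shorter sequence length, the coverage-corrected convention of
#' non-redundancy pipelines) are checked with the package's own aligner; a
#' query exceeding the ceiling against any training query is regenerated
#' up to `max_attempts` times.
#'
#' @param params A [family_params()] (its `seed` seeds the whole
#'   benchmark).
#' @param n_queries Total number of queries.
#' @param test_fraction Fraction of queries held out for testing.
#' @param identity_ceiling Maximum allowed identity between any test and
#'   any training query (1 disables the check).
#' @param max_attempts Regeneration attempts per offending query before a
#'   generation-failure error.
#' @return List with `train` / `test` (each a list of family `query`
#'   records), `targets`, `target_sse` (pooled library), and `alphabet`.
#' @export
generate_benchmark <- function(params = family_params(), n_queries = 12L,
                               test_fraction = 0.33,
                               identity_ceiling = 1.0,
                               max_attempts = 20L) {
  stopifnot(n_queries >= 2, test_fraction > 0, test_fraction < 1)
  families <- vector("list", n_queries)
  for (i in seq_len(n_queries)) {
    pi <- params
    pi$seed <- params$seed + i * 101L
    families[[i]] <- generate_family(pi, query_id = sprintf("q%02d", i))
  }
  n_test <- max(1L, round(test_fraction * n_queries))
  set.seed(params$seed)
  test_idx <- sort(sample.int(n_queries, n_test))
  train_idx <- setdiff(seq_len(n_queries), test_idx)
  if (identity_ceiling < 1) {
    sp <- search_params(min_aligned_length = 10L, min_identity = 0)
    for (ti in test_idx) {
      attempt <- 0L
      repeat {
        train_seqs <- stats::setNames(
          vapply(families[train_idx], function(f) f$query$seq, character(1)),
          vapply(families[train_idx], function(f) f$query$id, character(1)))
        worst <- max(vapply(seq_along(train_seqs), function(k)
          cross_set_identity(
            stats::setNames(families[[ti]]$query$seq,
                            families[[ti]]$query$id),
            train_seqs[k], sp), numeric(1)))
        if (worst <= identity_ceiling) break
        attempt <- attempt + 1L
        if (attempt > max_attempts)
          stop("generation failure: identity ceiling ", identity_ceiling,
               " infeasible after ", max_attempts, " attempts",
               call. = FALSE)
        pi <- params
        pi$seed <- params$seed + ti * 101L + attempt * 7919L
        families[[ti]] <- generate_family(pi,
                                          query_id = sprintf("q%02d", ti))
      }
    }
  }
  pool_targets <- do.call(c, lapply(families, `[[`, "targets"))
  pool_sse <- do.call(c, lapply(families, `[[`, "target_sse"))
  list(train = lapply(families[train_idx], `[[`, "query"),
       test = lapply(families[test_idx], `[[`, "query"),
       targets = pool_targets, target_sse = pool_sse,
       alphabet = params$alphabet)
}
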