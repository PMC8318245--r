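# Local similarity search: a self-contained aligner producing the hit list
# an external search engine (PSI-BLAST, HHBlits) would supply. Alignment is
# optimal local with affine gaps (Biostrings); one best alignment per target.

#' Search parameters
#'
#' @param match_score,mismatch_score Substitution scores for identical /
#'   differing residues ('X' never matches, including itself).
#' @param gap_open,gap_extend Affine gap penalties (<= 0); a gap of length
#'   L costs `gap_open + L * gap_extend`.
#' @param min_identity Minimum identity fraction in `[0, 1]` for a hit to
#'   be reported.
#' @param min_aligned_length Minimum number of aligned (gap-free) columns.
#' @param max_hits Maximum number of hits returned.
#' @return A list of class `search_params`.
#' @export
search_params <- function(match_score = 2, mismatch_score = -1,
                          gap_open = -11, gap_extend = -1,
                          min_identity = 0, min_aligned_length = 10L,
                          max_hits = 500L) {
  stopifnot(gap_open <= 0, gap_extend <= 0,
            min_identity >= 0, min_identity <= 1, max_hits >= 1)
  structure(list(match_score = match_score, mismatch_score = mismatch_score,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_identity = min_identity,
                 min_aligned_length = as.integer(min_aligned_length),
                 max_hits = as.integer(max_hits)),
            class = "search_params")
}

.aa_chars <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

.sub_matrix <- function(params) {
  m <- matrix(params$mismatch_score, length(.aa_chars), length(.aa_chars),
              dimnames = list(.aa_chars, .aa_chars))
  diag(m) <- params$match_score
  m["X", "X"] <- params$mismatch_score  # unknown never matches
  m
}

# identity = matched columns / columns where neither side is a gap
alignment_identity <- function(query_aln, hit_aln) {
  q <- strsplit(query_aln, "")[[1]]
  h <- strsplit(hit_aln, "")[[1]]
  stopifnot(length(q) == length(h))
  both <- q != "-" & h != "-"
  if (!any(both)) return(0)
  sum(q[both] == h[both]) / sum(both)
}

# Recompute the affine-gap score of a given pairwise alignment; used by the
# search invariant that every reported score equals its alignment's score.
score_alignment <- function(query_aln, hit_aln, params = search_params()) {
  q <- strsplit(query_aln, "")[[1]]
  h <- strsplit(hit_aln, "")[[1]]
  stopifnot(length(q) == length(h))
  s <- 0
  in_gap <- FALSE
  for (i in seq_along(q)) {
    if (q[i] == "-" || h[i] == "-") {
      if (!in_gap) s <- s + params$gap_open
      s <- s + params$gap_extend
      in_gap <- TRUE
    } else {
      s <- s + if (q[i] == h[i] && q[i] != "X")
        params$match_score else params$mismatch_score
      in_gap <- FALSE
    }
  }
  s
}

#' Search a query against a target set
#'
#' Computes the single best local alignment (affine gap penalties) of the
#' query against every target, filters by identity and aligned length, and
#' returns hits sorted by alignment score (descending), ties broken by hit
#' id (ascending). Deterministic: no randomness is involved.
#'
#' @param query Single named character (the query sequence; its name is the
#'   query id) or an unnamed string with `query_id` supplied.
#' @param targets Named character vector of target sequences.
#' @param params A [search_params()].
#' @param query_id Query id when `query` is unnamed.
#' @return A `data.frame` (one row per hit) with columns `query_id`,
#'   `hit_id`, `query_aln`, `hit_aln`, `identity`, `score`, `q_start`,
#'   `h_start` (1-based starts of the aligned regions). Zero rows when no
#'   target yields a positive-scoring alignment passing the filters.
#' @export
search_homologs <- function(query, targets, params = search_params(),
                            query_id = names(query)) {
  if (length(targets) == 0L) stop("empty target set", call. = FALSE)
  stopifnot(length(query) == 1L, nzchar(query))
  if (is.null(query_id)) query_id <- "query"
  sm <- .sub_matrix(params)
  alns <- Biostrings::pairwiseAlignment(
    pattern = rep(unname(query), length(targets)),
    subject = Biostrings::BStringSet(unname(targets)),
    type = "local", substitutionMatrix = sm,
    gapOpening = abs(params$gap_open), gapExtension = abs(params$gap_extend))
  res <- data.frame(
    query_id = query_id,
    hit_id = names(targets),
    query_aln = as.character(Biostrings::pattern(alns)),
    hit_aln = as.character(Biostrings::subject(alns)),
    identity = NA_real_,
    score = Biostrings::score(alns),
    q_start = BiocGenerics::start(Biostrings::pattern(alns)),
    h_start = BiocGenerics::start(Biostrings::subject(alns)),
    stringsAsFactors = FALSE)
  keep <- res$score > 0 & nzchar(res$query_aln)
  res <- res[keep, , drop = FALSE]
  if (nrow(res)) {
    res$identity <- mapply(alignment_identity, res$query_aln, res$hit_aln,
                           USE.NAMES = FALSE)
    ncols <- mapply(function(q, h) {
      qs <- strsplit(q, "")[[1]]; hs <- strsplit(h, "")[[1]]
      sum(qs != "-" & hs != "-")
    }, res$query_aln, res$hit_aln, USE.NAMES = FALSE)
    res <- res[res$identity >= params$min_identity &
                 ncols >= params$min_aligned_length, , drop = FALSE]
  }
  res <- res[order(-res$score, res$hit_id), , drop = FALSE]
  if (nrow(res) > params$max_hits)
    res <- res[seq_len(params$max_hits), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hit weight for occurrence counting
#'
#' The per-hit weight W(h) entering the occurrence sums is the hit's
#' sequence identity fraction with the query, so that closer homologs
#' contribute more to the profile.
#'
#' @param hit One row of a [search_homologs()] result (or any list with an
#'   `identity` element), or a bare numeric identity.
#' @return Weight in `[0, 1]`.
#' @export
hit_weight <- function(hit) {
  w <- if (is.numeric(hit)) hit else hit$identity
  stopifnot(all(w >= 0 & w <= 1))
  unname(w)
}
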