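# SSE string acquisition for hits: direct lookup when the hit's structure
# annotation is in the library, otherwise a synthesized representative via
# position-specific voting over the hit's own homologs (second-round
# search against a reference set of annotated structures).

#' Structure-annotation library
#'
#' Maps protein ids to their SSE strings (as computed from known
#' structures, e.g. by DSSP upstream of this package).
#'
#' @param sse Named character vector of SSE strings (ids as names).
#' @param alphabet [sse_alphabet()] or registered name.
#' @return An object of class `sse_library`.
#' @export
sse_library <- function(sse, alphabet) {
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  sse <- vapply(seq_along(sse), function(i)
    validate_sse_string(sse[[i]], alphabet, id = names(sse)[i]),
    character(1)) |> stats::setNames(names(sse))
  structure(list(sse = sse, alphabet = alphabet), class = "sse_library")
}

#' Voting parameters for representative-SSE synthesis
#'
#' @param alphabet [sse_alphabet()] or name.
#' @param tie_break_order Permutation of the alphabet codes; a tied vote is
#'   awarded to the earliest code in this order. Default `NULL` defers to
#'   the reference library's descending background frequency (ties
#'   alphabetical), preferring the a-priori likelier conformation.
#' @param uncovered_code Code assigned to residues aligned with no homolog
#'   residue; default `"C"`, the least structurally committed call.
#' @param search_params [search_params()] for the second-round search.
#' @param weighted Weight votes by second-round alignment identity (the
#'   same W(h) as occurrence counting)? `FALSE` gives one vote per aligned
#'   residue.
#' @return A list of class `vote_params`.
#' @export
vote_params <- function(alphabet = "dssp8", tie_break_order = NULL,
                        uncovered_code = "C",
                        search_params = ssepssm::search_params(),
                        weighted = TRUE) {
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  if (!is.null(tie_break_order)) {
    if (!setequal(tie_break_order, alphabet$codes) ||
        length(tie_break_order) != length(alphabet$codes))
      stop("`tie_break_order` must be a permutation of the alphabet codes",
           call. = FALSE)
  }
  if (!uncovered_code %in% alphabet$codes)
    stop("`uncovered_code` must be an alphabet code", call. = FALSE)
  structure(list(alphabet = alphabet, tie_break_order = tie_break_order,
                 uncovered_code = uncovered_code,
                 search_params = search_params, weighted = weighted),
            class = "vote_params")
}

# Tie-break order derived from a library: codes by descending background
# frequency, then alphabetically.
default_tie_break_order <- function(library) {
  bg <- compute_background(library, library$alphabet)
  codes <- library$alphabet$codes
  codes[order(-bg[codes], codes)]
}

#' Weighted vote over the SSE codes aligned with one residue
#'
#' Returns the code with the largest summed weight; ties are broken by the
#' configured tie-break order. An empty column (residue covered by no
#' homolog) returns the uncovered code.
#'
#' @param codes Character vector of SSE codes aligned with the residue.
#' @param weights Non-negative numeric vector, same length as `codes`.
#' @param params A [vote_params()] (with a concrete `tie_break_order`).
#' @return A single SSE code.
#' @export
vote_column <- function(codes, weights, params) {
  stopifnot(length(codes) == length(weights), all(weights >= 0))
  if (length(codes) == 0L) return(params$uncovered_code)
  order_codes <- params$tie_break_order %||% params$alphabet$codes
  tally <- vapply(order_codes, function(cd) sum(weights[codes == cd]),
                  numeric(1))
  if (all(tally == 0)) return(params$uncovered_code)
  order_codes[which.max(tally)]  # which.max takes the first maximum
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' SSE string of a hit: lookup or representative-by-vote synthesis
#'
#' When the hit id is present in the structure library its annotated SSE
#' string is returned verbatim. Otherwise a second-round similarity search
#' of the hit sequence against `reference_targets` (all of which must be
#' annotated in the library) is run, and each hit residue receives the
#' weighted-vote winner among the SSE codes of the homolog residues aligned
#' with it; residues covered by no homolog receive the uncovered code.
#'
#' @param hit_id Protein id of the hit.
#' @param hit_sequence The hit's amino-acid sequence.
#' @param library An [sse_library()].
#' @param reference_targets Named character vector of reference sequences
#'   (each id present in `library`).
#' @param params A [vote_params()].
#' @return SSE string of length `nchar(hit_sequence)`.
#' @export
get_sse <- function(hit_id, hit_sequence, library, reference_targets = NULL,
                    params = vote_params(library$alphabet)) {
  stopifnot(inherits(library, "sse_library"), nzchar(hit_sequence))
  if (hit_id %in% names(library$sse)) return(library$sse[[hit_id]])
  if (is.null(reference_targets))
    stop("hit '", hit_id, "' is not annotated and no reference targets ",
         "were given", call. = FALSE)
  missing_ann <- setdiff(names(reference_targets), names(library$sse))
  if (length(missing_ann))
    stop("reference target(s) absent from the SSE library: ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  if (is.null(params$tie_break_order))
    params$tie_break_order <- default_tie_break_order(library)
  hits <- search_homologs(stats::setNames(hit_sequence, hit_id),
                          reference_targets, params$search_params)
  n <- nchar(hit_sequence)
  votes <- vector("list", n)
  for (i in seq_len(nrow(hits))) {
    tr <- transform_alignment(
      hits$query_aln[i], hits$hit_aln[i],
      library$sse[[hits$hit_id[i]]],
      weight = if (params$weighted) hits$identity[i] else 1,
      hit_id = hits$hit_id[i], hit_start = hits$h_start[i],
      q_start = hits$q_start[i])
    q <- strsplit(tr$query_aln, "")[[1]]
    s <- strsplit(tr$sse_aln, "")[[1]]
    qpos <- tr$q_start - 1L
    for (j in seq_along(q)) {
      if (q[j] != "-") {
        qpos <- qpos + 1L
        if (s[j] != "-")
          votes[[qpos]] <- rbind(votes[[qpos]],
                                 data.frame(code = s[j], w = tr$weight))
      }
    }
  }
  out <- vapply(votes, function(v) {
    if (is.null(v)) params$uncovered_code
    else vote_column(v$code, v$w, params)
  }, character(1))
  paste(out, collapse = "")
}

#' Assign SSE strings to a set of hits
#'
#' Vectorized front end to [get_sse()]: looks up or synthesizes the SSE
#' string of every hit sequence.
#'
#' @param hit_seqs Named character vector of hit sequences.
#' @inheritParams get_sse
#' @return Named character vector of SSE strings.
#' @export
assign_sse <- function(hit_seqs, library, reference_targets = NULL,
                       params = vote_params(library$alphabet)) {
  out <- vapply(names(hit_seqs), function(id)
    get_sse(id, hit_seqs[[id]], library, reference_targets, params),
    character(1))
  stats::setNames(out, names(hit_seqs))
}
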