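# The heart of the method: SSE transformation of pairwise alignments,
# identity-weighted code occurrences, the position propensity matrix (PPM),
# the log2 log-odds PSSM, background frequencies, the pseudocount fallback,
# and BLOSUM-style construction of an SSE substitution matrix.

#' SSE-transform a pairwise alignment
#'
#' Replaces, residue by residue, the amino-acid characters of the aligned
#' hit string with that hit's SSE codes, preserving the gap structure. For
#' a hit with amino acids `"ILGWL"` and SSE `"CHHEE"` aligned as
#' `"IL-GW--L"`, the transformed string is `"CH-HE--E"`.
#'
#' @param query_aln,hit_aln Gapped aligned strings of equal length.
#' @param hit_sse The hit's full (unaligned) SSE string.
#' @param weight Hit weight W(h) in `[0, 1]` (see [hit_weight()]).
#' @param hit_id Optional hit identifier carried through.
#' @param hit_start 1-based position of the first aligned hit residue
#'   within the full hit sequence (1 for global/gapless alignments; the
#'   `h_start` column of [search_homologs()] output for local ones).
#' @param hit_sequence Optional full hit amino-acid sequence; when given,
#'   `hit_sse` must have the same length and `hit_start` is located
#'   automatically if not supplied.
#' @param q_start 1-based query position of the first aligned query
#'   residue (carried through for occurrence counting).
#' @return An object of class `transformed_alignment`: list with
#'   `query_aln`, `sse_aln`, `weight`, `hit_id`, `q_start`.
#' @export
transform_alignment <- function(query_aln, hit_aln, hit_sse, weight,
                                hit_id = NA_character_, hit_start = 1L,
                                hit_sequence = NULL, q_start = 1L) {
  stopifnot(nchar(query_aln) == nchar(hit_aln),
            weight >= 0, weight <= 1)
  degapped <- gsub("-", "", hit_aln, fixed = TRUE)
  if (!is.null(hit_sequence)) {
    if (nchar(hit_sse) != nchar(hit_sequence))
      stop("length mismatch: hit SSE has ", nchar(hit_sse),
           " codes but hit sequence has ", nchar(hit_sequence),
           " residues", call. = FALSE)
    if (missing(hit_start)) {
      hit_start <- as.integer(regexpr(degapped, hit_sequence, fixed = TRUE))
      if (hit_start < 1L)
        stop("de-gapped hit alignment is not a substring of the hit ",
             "sequence", call. = FALSE)
    }
  }
  if (hit_start + nchar(degapped) - 1L > nchar(hit_sse))
    stop("length mismatch: aligned hit region [", hit_start, ", ",
         hit_start + nchar(degapped) - 1L, "] exceeds SSE length ",
         nchar(hit_sse), call. = FALSE)
  h <- strsplit(hit_aln, "")[[1]]
  sse <- strsplit(hit_sse, "")[[1]]
  out <- h
  out[h != "-"] <- sse[seq(hit_start, length.out = sum(h != "-"))]
  structure(list(query_aln = query_aln,
                 sse_aln = paste(out, collapse = ""),
                 weight = weight, hit_id = hit_id,
                 q_start = as.integer(q_start)),
            class = "transformed_alignment")
}

#' Weighted SSE code occurrences per query position
#'
#' For every residue position p of the query, sums the weights of hits
#' whose aligned residue carries each code c:
#' `Occ(c, p) = sum_h 1[Code(h, p) = c] * W(h)`. Hit-side gaps contribute
#' nothing; a position aligned with no hit residue has an all-zero row.
#'
#' @param query The ungapped query sequence (string) or its length.
#' @param transformed List of `transformed_alignment` objects.
#' @param alphabet [sse_alphabet()] or registered name.
#' @param unknown_action What to do with aligned codes outside the
#'   alphabet: `"error"` (default; SSE strings admit no unknown code) or
#'   `"skip"` (used for the amino-acid profile, where 'X' is legal in
#'   sequences but carries no occurrence mass).
#' @return An `occurrence_matrix`: numeric matrix, query length x alphabet
#'   size, with the codes as column names.
#' @export
compute_occurrences <- function(query, transformed, alphabet,
                                unknown_action = c("error", "skip")) {
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  unknown_action <- match.arg(unknown_action)
  n <- if (is.character(query)) nchar(query) else as.integer(query)
  k <- length(alphabet$codes)
  occ <- matrix(0, n, k, dimnames = list(NULL, alphabet$codes))
  for (tr in transformed) {
    q <- strsplit(tr$query_aln, "")[[1]]
    s <- strsplit(tr$sse_aln, "")[[1]]
    qpos <- tr$q_start - 1L
    for (i in seq_along(q)) {
      if (q[i] != "-") {
        qpos <- qpos + 1L
        if (s[i] != "-") {
          if (qpos > n)
            stop("alignment references query position ", qpos,
                 " beyond query length ", n, call. = FALSE)
          j <- match(s[i], alphabet$codes)
          if (is.na(j)) {
            if (unknown_action == "error")
              stop("invalid code '", s[i], "' for alphabet '",
                   alphabet$name, "' in transformed alignment", call. = FALSE)
          } else {
            occ[qpos, j] <- occ[qpos, j] + tr$weight
          }
        }
      }
    }
  }
  structure(occ, class = c("occurrence_matrix", class(occ)))
}

#' Background SSE code frequencies of a reference library
#'
#' Pools code counts over every residue of every string in the library.
#' When any code of the alphabet is absent from the pooled counts, add-one
#' smoothing (one count to every code) keeps all frequencies strictly
#' positive, as the log-odds denominator requires.
#'
#' @param library Named character vector of SSE strings (or an
#'   `sse_library`).
#' @param alphabet [sse_alphabet()] or registered name.
#' @return A named numeric vector of class `background_freqs` summing to 1.
#' @export
compute_background <- function(library, alphabet) {
  if (inherits(library, "sse_library")) {
    alphabet <- library$alphabet
    library <- library$sse
  }
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  if (length(library) == 0L) stop("empty SSE library", call. = FALSE)
  chars <- strsplit(paste(library, collapse = ""), "")[[1]]
  counts <- table(factor(chars[chars != "-"], levels = alphabet$codes))
  counts <- as.numeric(counts)
  if (any(counts == 0)) counts <- counts + 1
  structure(stats::setNames(counts / sum(counts), alphabet$codes),
            class = "background_freqs")
}

#' Position propensity matrix from occurrences
#'
#' Normalizes each occurrence row into a frequency vector:
#' `PPM(s, p) = Occ(s, p) / sum_c Occ(c, p)`. Positions where no hit
#' residue aligns (all-zero rows) are filled with the background
#' frequencies and recorded as fallback positions.
#'
#' @param occ An `occurrence_matrix`.
#' @param background [compute_background()] result (required only when
#'   fallback positions exist).
#' @return List with `ppm` (rows sum to 1) and `pseudocount_positions`
#'   (integer vector of fallback positions).
#' @export
ppm_from_occurrences <- function(occ, background = NULL) {
  rs <- rowSums(occ)
  empty <- which(rs == 0)
  ppm <- occ / ifelse(rs > 0, rs, 1)
  if (length(empty)) {
    if (is.null(background))
      stop("positions with no aligned residue require `background`",
           call. = FALSE)
    ppm[empty, ] <- rep(background[colnames(occ)], each = length(empty))
  }
  list(ppm = unclass(ppm), pseudocount_positions = as.integer(empty))
}

# Conditional substitution probabilities T(c | c') recovered from a
# substitution matrix: invert the log-odds to joint pair frequencies
# q_ab = e_ab * 2^score, with e_ab the background-expected frequencies,
# then condition on the columns.
conditional_substitution_probs <- function(subst) {
  stopifnot(inherits(subst, "sse_substitution_matrix"))
  codes <- subst$alphabet$codes
  p <- subst$background[codes]
  e <- outer(p, p)
  e[lower.tri(e) | upper.tri(e)] <- 2 * e[lower.tri(e) | upper.tri(e)]
  q <- e * 2^subst$scores[codes, codes]
  # joint matrix: off-diagonal unordered-pair mass split over both cells
  joint <- q
  joint[lower.tri(joint) | upper.tri(joint)] <-
    joint[lower.tri(joint) | upper.tri(joint)] / 2
  joint <- joint / sum(joint)
  sweep(joint, 2, colSums(joint), "/")  # T[c, c'] = P(c | c')
}

#' Pseudocount smoothing of one occurrence column
#'
#' Henikoff-style mixture of the observed position frequencies with a
#' substitution-matrix-derived prior:
#' `f'_c = (N_p * f_c + tau * g_c) / (N_p + tau)` where `N_p` is the total
#' occurrence mass at the position, `f_c = Occ(c, p) / N_p`, and
#' `g_c = sum_c' f_c' * T(c | c')` with `T` the conditional substitution
#' probabilities derived from `subst`. When `N_p = 0` the prior cannot be
#' formed (the query's own SSE is unknown) and the background is returned.
#'
#' @param occ_col Named numeric vector of occurrences for one position.
#' @param background [compute_background()] result.
#' @param subst An `sse_substitution_matrix`.
#' @param tau Pseudocount mass (>= 0); 0 disables smoothing.
#' @return Frequency vector summing to 1 (strictly positive when
#'   `tau > 0`).
#' @export
apply_pseudocounts <- function(occ_col, background, subst, tau = 0.5) {
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  codes <- names(occ_col)
  np <- sum(occ_col)
  if (np == 0) return(stats::setNames(as.numeric(background[codes]), codes))
  f <- occ_col / np
  if (tau == 0) return(f)
  tmat <- conditional_substitution_probs(subst)[codes, codes]
  g <- as.numeric(tmat %*% f)
  out <- (np * f + tau * g) / (np + tau)
  stats::setNames(out / sum(out), codes)
}

#' Log-odds PSSM from a PPM
#'
#' `PSSM(s, p) = log2(PPM(s, p) / B_s)` with `B` the background
#' frequencies. Zero PPM cells (possible only with `tau = 0`) map to a
#' finite floor so matrices stay serializable.
#'
#' @param ppm Positions x codes frequency matrix.
#' @param background [compute_background()] result (strictly positive).
#' @param floor Score assigned to zero-probability cells (default -10
#'   bits).
#' @return Matrix of the same shape.
#' @export
pssm_from_ppm <- function(ppm, background, floor = -10) {
  b <- as.numeric(background[colnames(ppm)])
  if (any(!is.finite(b)) || any(b <= 0))
    stop("background frequencies must be strictly positive", call. = FALSE)
  out <- log2(sweep(ppm, 2, b, "/"))
  out[ppm == 0] <- floor
  out
}

#' Build an SSE (or amino-acid) profile for a query
#'
#' Composes the full pipeline for one query: SSE transformation of each hit
#' alignment, weighted occurrence counting, pseudocounted PPM, and log-odds
#' PSSM. Run with the `aa20` alphabet and the hit amino-acid sequences in
#' place of SSE strings, the identical code path produces the classic
#' AA-PSSM (see [build_aa_profile()]).
#'
#' @param query Single named character (query sequence).
#' @param hits Hit table from [search_homologs()] or [read_alignment_tsv()]
#'   (columns `hit_id`, `query_aln`, `hit_aln`, `identity`, optionally
#'   `q_start`/`h_start`). May have zero rows.
#' @param hit_sse Named character vector: full SSE string per hit id (from
#'   an [sse_library()] lookup or [assign_sse()]).
#' @param alphabet [sse_alphabet()] or name.
#' @param background [compute_background()] result.
#' @param subst `sse_substitution_matrix` driving the pseudocount prior
#'   (required when `tau > 0`).
#' @param tau Pseudocount mass; default 0.5.
#' @param hit_seqs Optional named character vector of full hit sequences,
#'   used to locate aligned regions when `h_start` is absent and to check
#'   SSE lengths.
#' @param floor PSSM floor for zero cells.
#' @param unknown_action Passed to [compute_occurrences()].
#' @return An object of class `sse_profile`: list with `query_id`, `query`,
#'   `alphabet`, `occ`, `ppm`, `pssm`, `background`,
#'   `pseudocount_positions`, `tau`.
#' @export
build_profile <- function(query, hits, hit_sse, alphabet, background,
                          subst = NULL, tau = 0.5, hit_seqs = NULL,
                          floor = -10,
                          unknown_action = c("error", "skip")) {
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  unknown_action <- match.arg(unknown_action)
  if (tau > 0 && is.null(subst))
    stop("`subst` is required when `tau` > 0", call. = FALSE)
  query_id <- if (!is.null(names(query))) names(query)[1] else "query"
  qseq <- unname(query[1])
  transformed <- lapply(seq_len(nrow(hits)), function(i) {
    hid <- hits$hit_id[i]
    if (!hid %in% names(hit_sse))
      stop("no SSE string for hit '", hid, "'", call. = FALSE)
    q_start <- if ("q_start" %in% names(hits)) hits$q_start[i] else {
      ps <- regexpr(gsub("-", "", hits$query_aln[i], fixed = TRUE), qseq,
                    fixed = TRUE)
      if (ps < 1L) stop("de-gapped query alignment of hit '", hid,
                        "' is not a substring of the query", call. = FALSE)
      as.integer(ps)
    }
    if ("h_start" %in% names(hits)) {
      transform_alignment(hits$query_aln[i], hits$hit_aln[i],
                          hit_sse[[hid]], hit_weight(hits$identity[i]),
                          hit_id = hid, hit_start = hits$h_start[i],
                          hit_sequence = hit_seqs[[hid]], q_start = q_start)
    } else {
      transform_alignment(hits$query_aln[i], hits$hit_aln[i],
                          hit_sse[[hid]], hit_weight(hits$identity[i]),
                          hit_id = hid, hit_sequence = hit_seqs[[hid]],
                          q_start = q_start)
    }
  })
  occ <- compute_occurrences(qseq, transformed, alphabet,
                             unknown_action = unknown_action)
  np <- rowSums(occ)
  if (tau > 0) {
    ppm <- t(apply(occ, 1, apply_pseudocounts, background = background,
                   subst = subst, tau = tau))
    colnames(ppm) <- alphabet$codes
    pc_pos <- as.integer(which(np == 0))
  } else {
    res <- ppm_from_occurrences(occ, background)
    ppm <- res$ppm
    pc_pos <- res$pseudocount_positions
  }
  pssm <- pssm_from_ppm(ppm, background, floor = floor)
  structure(list(query_id = query_id, query = qseq, alphabet = alphabet,
                 occ = unclass(occ), ppm = ppm, pssm = pssm,
                 background = background,
                 pseudocount_positions = pc_pos, tau = tau),
            class = "sse_profile")
}

#' @export
print.sse_profile <- function(x, ...) {
  cat("SSE profile for '", x$query_id, "': ", nchar(x$query),
      " residues x ", length(x$alphabet$codes), " codes ('",
      x$alphabet$name, "'), tau = ", x$tau, ", ",
      length(x$pseudocount_positions), " background-fallback position(s)\n",
      sep = "")
  invisible(x)
}

#' Build the classic amino-acid PSSM over the same machinery
#'
#' Convenience wrapper around [build_profile()] with the `aa20` alphabet:
#' the "SSE" strings of the hits are their amino-acid sequences, so the
#' occurrence/PPM/PSSM pipeline yields the traditional AA-PSSM. Unknown
#' residues ('X') contribute no occurrence mass.
#'
#' @inheritParams build_profile
#' @param hit_seqs Named character vector of full hit sequences.
#' @export
build_aa_profile <- function(query, hits, hit_seqs, background,
                             subst = NULL, tau = 0, floor = -10) {
  build_profile(query, hits, hit_sse = hit_seqs,
                alphabet = sse_alphabet("aa20"), background = background,
                subst = subst, tau = tau, hit_seqs = hit_seqs,
                floor = floor, unknown_action = "skip")
}

new_substitution_matrix <- function(alphabet, scores, background) {
  structure(list(alphabet = alphabet, scores = scores,
                 background = background),
            class = "sse_substitution_matrix")
}

#' BLOSUM-style substitution matrix from aligned SSE pairs
#'
#' Applies the BLOSUM estimation procedure to a corpus of gapped, aligned
#' SSE string pairs: observed unordered pair frequencies `q_ab` over all
#' gap-free columns (both orders pooled), marginals
#' `p_a = q_aa + sum_{b != a} q_ab / 2`, expected frequencies
#' `e_aa = p_a^2` and `e_ab = 2 p_a p_b` (a != b), and scores
#' `log2(q_ab / e_ab)`. Columns containing a gap on either side are
#' skipped. Never-observed pairs receive a finite floor score.
#'
#' @param aligned_pairs List of length-2 character vectors (or a 2-column
#'   data frame / matrix) of equal-length gapped SSE strings.
#' @param alphabet [sse_alphabet()] or name.
#' @param floor Score for pairs with zero observed frequency (default -10).
#' @return An `sse_substitution_matrix`: list with `alphabet`, symmetric
#'   `scores` matrix (bits) and marginal `background` vector.
#' @export
build_substitution_matrix <- function(aligned_pairs, alphabet, floor = -10) {
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  if (is.data.frame(aligned_pairs) || is.matrix(aligned_pairs))
    aligned_pairs <- lapply(seq_len(nrow(aligned_pairs)),
                            function(i) as.character(aligned_pairs[i, 1:2]))
  codes <- alphabet$codes
  k <- length(codes)
  counts <- matrix(0, k, k, dimnames = list(codes, codes))
  for (pr in aligned_pairs) {
    a <- strsplit(pr[[1]], "")[[1]]
    b <- strsplit(pr[[2]], "")[[1]]
    if (length(a) != length(b))
      stop("aligned pair strings have unequal length", call. = FALSE)
    keep <- a != "-" & b != "-"
    a <- a[keep]; b <- b[keep]
    ia <- match(a, codes); ib <- match(b, codes)
    if (anyNA(ia) || anyNA(ib))
      stop("aligned pair contains a code outside alphabet '",
           alphabet$name, "'", call. = FALSE)
    for (i in seq_along(ia)) {
      lo <- min(ia[i], ib[i]); hi <- max(ia[i], ib[i])
      counts[lo, hi] <- counts[lo, hi] + 1
    }
  }
  total <- sum(counts)
  if (total == 0) stop("no usable (gap-free) aligned columns", call. = FALSE)
  q <- counts / total                       # unordered pair frequencies
  q[lower.tri(q)] <- t(q)[lower.tri(q)]     # mirror for lookup
  p <- diag(q) + (rowSums(q) - diag(q)) / 2 # marginals
  e <- 2 * outer(p, p)
  diag(e) <- p^2
  scores <- matrix(floor, k, k, dimnames = list(codes, codes))
  pos <- q > 0 & e > 0
  scores[pos] <- log2(q[pos] / e[pos])
  bg <- p
  if (any(bg == 0)) bg <- (bg * total + 1) / (total + k)  # add-one smoothing
  new_substitution_matrix(alphabet, scores, stats::setNames(bg, codes))
}

#' @export
print.sse_substitution_matrix <- function(x, ...) {
  cat("SSE substitution matrix over '", x$alphabet$name, "' (bits):\n",
      sep = "")
  print(round(x$scores, 2))
  invisible(x)
}
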