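# Per-residue machine-learning features: sliding-window spanning of
# profile matrices, the single-integer amino-acid-type encoding, feature
# merging, and import of external predictors' per-residue outputs.

#' Sliding-window features from a per-position matrix
#'
#' Row p of the output is the concatenation of input rows p-k .. p+k with
#' k = (window_size - 1) / 2; out-of-range positions are filled with
#' `pad_value`. A window of 5 residues is the default: in sweeps over
#' window sizes 1-21, segment-overlap accuracy peaks there while the
#' feature count stays small.
#'
#' @param m Numeric matrix, positions x per-position features (e.g. the
#'   `pssm` of an `sse_profile`).
#' @param window_size Odd integer >= 1.
#' @param pad_value Fill for out-of-range cells; 0 is the natural choice
#'   for log-odds scores (zero = background).
#' @return Matrix of class `feature_matrix`, positions x
#'   `window_size * ncol(m)`, column names `<col>.w<offset>`.
#' @export
window_features <- function(m, window_size = 5L, pad_value = 0) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 1)
  window_size <- as.integer(window_size)
  if (window_size < 1L || window_size %% 2L == 0L)
    stop("`window_size` must be an odd integer >= 1", call. = FALSE)
  k <- (window_size - 1L) %/% 2L
  n <- nrow(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  blocks <- lapply(-k:k, function(off) {
    idx <- seq_len(n) + off
    block <- matrix(pad_value, n, ncol(m))
    ok <- idx >= 1L & idx <= n
    block[ok, ] <- m[idx[ok], , drop = FALSE]
    colnames(block) <- paste0(colnames(m), ".w", off)
    block
  })
  out <- do.call(cbind, blocks)
  structure(out, class = c("feature_matrix", class(out)))
}

# Amino-acid type encoding table, built from: five side-chain
# physiochemical classes, classes ordered by mean Kyte-Doolittle
# hydropathy high -> low, residues within a class ordered by natural
# abundance (Swiss-Prot frequencies) low -> high, integers 1..20 assigned
# in that order. 'X' (unknown) is the 0 sentinel.
.aa_type_table <- local({
  classes <- list(
    nonpolar_aliphatic  = c("G", "A", "P", "V", "L", "I", "M"),
    aromatic            = c("F", "Y", "W"),
    polar_uncharged     = c("S", "T", "C", "N", "Q"),
    positively_charged  = c("K", "R", "H"),
    negatively_charged  = c("D", "E"))
  kd <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
          G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
          H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9,
          R = -4.5)
  abundance <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38,
                 Q = 3.93, E = 6.72, G = 7.08, H = 2.27, I = 5.91,
                 L = 9.65, K = 5.80, M = 2.41, F = 3.86, P = 4.73,
                 S = 6.63, T = 5.35, W = 1.10, Y = 2.92, V = 6.86)
  class_hydro <- vapply(classes, function(aas) mean(kd[aas]), numeric(1))
  ordered_classes <- names(classes)[order(-class_hydro)]
  aas <- unlist(lapply(ordered_classes, function(cl) {
    members <- classes[[cl]]
    members[order(abundance[members])]
  }), use.names = FALSE)
  data.frame(aa = aas, code = seq_along(aas),
             class = rep(ordered_classes,
                         vapply(classes[ordered_classes], length,
                                integer(1))),
             hydropathy = unname(kd[aas]),
             abundance = unname(abundance[aas]),
             stringsAsFactors = FALSE)
})

#' Amino-acid type encoding table
#'
#' The table behind [encode_amino_acid()], with the class, hydropathy and
#' abundance values that determine the ordering. The table is a
#' reconstruction from its stated construction procedure, regenerated in
#' code rather than shipped as opaque data.
#'
#' @return Data frame with columns `aa`, `code`, `class`, `hydropathy`,
#'   `abundance`.
#' @export
amino_acid_encoding <- function() .aa_type_table

#' Encode amino acids as single integers
#'
#' A fixed bijection of the 20 standard amino acids onto 1..20 built so
#' that physiochemically similar residues receive nearby integers: five
#' side-chain classes sorted by hydrophobicity (high to low), residues
#' within a class by natural abundance (low to high). `X` maps to 0.
#'
#' @param aa Character vector of single letters, or one string of
#'   residues.
#' @return Integer vector, one code per residue.
#' @export
encode_amino_acid <- function(aa) {
  if (length(aa) == 1L && nchar(aa) > 1L) aa <- strsplit(aa, "")[[1]]
  codes <- stats::setNames(.aa_type_table$code, .aa_type_table$aa)
  out <- unname(codes[aa])
  out[aa == "X"] <- 0L
  if (anyNA(out))
    stop("invalid residue '", aa[is.na(out) & aa != "X"][1], "'",
         call. = FALSE)
  as.integer(out)
}

#' Merge feature matrices column-wise
#'
#' Feature-set integration is a plain column-wise merge; names are
#' prefixed by source so provenance stays visible.
#'
#' @param sources Named list of matrices with equal row counts (names
#'   become column-name prefixes; unnamed sources are prefixed `src<i>`).
#' @return A `feature_matrix`.
#' @export
merge_features <- function(sources) {
  stopifnot(is.list(sources), length(sources) >= 1)
  nr <- vapply(sources, nrow, integer(1))
  if (length(unique(nr)) != 1L)
    stop("feature sources have differing residue counts: ",
         paste(nr, collapse = ", "), call. = FALSE)
  nms <- names(sources) %||% rep("", length(sources))
  nms[!nzchar(nms)] <- paste0("src", which(!nzchar(nms)))
  blocks <- lapply(seq_along(sources), function(i) {
    b <- as.matrix(sources[[i]])
    if (is.null(colnames(b))) colnames(b) <- paste0("f", seq_len(ncol(b)))
    colnames(b) <- paste0(nms[i], ".", colnames(b))
    b
  })
  out <- do.call(cbind, blocks)
  structure(out, class = c("feature_matrix", class(out)))
}

#' Import an external predictor's per-residue output as features
#'
#' Accepts either per-residue probability rows over the alphabet or a
#' single predicted label per residue. Labels become one-hot rows
#' (probability 1 for the predicted code, 0 elsewhere). Probability rows
#' are renormalized when their sum is within 1e-3 of 1 and rejected
#' otherwise.
#'
#' @param x Character vector of labels (or one SSE string), or a numeric
#'   matrix with `length(alphabet$codes)` columns.
#' @param alphabet [sse_alphabet()] or name.
#' @return A `feature_matrix`, residues x codes.
#' @export
import_external_prediction <- function(x, alphabet) {
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  codes <- alphabet$codes
  if (is.character(x)) {
    if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
    j <- match(x, codes)
    if (anyNA(j))
      stop("label '", x[is.na(j)][1], "' is not a code of alphabet '",
           alphabet$name, "'", call. = FALSE)
    out <- matrix(0, length(x), length(codes),
                  dimnames = list(NULL, codes))
    out[cbind(seq_along(j), j)] <- 1
  } else {
    x <- as.matrix(x)
    if (ncol(x) != length(codes))
      stop("probability rows must have ", length(codes), " columns for ",
           "alphabet '", alphabet$name, "'", call. = FALSE)
    sums <- rowSums(x)
    off <- abs(sums - 1) > 1e-3
    if (any(off))
      stop("malformed probabilities: row ", which(off)[1], " sums to ",
           format(sums[off][1]), call. = FALSE)
    out <- x / sums
    colnames(out) <- codes
  }
  structure(out, class = c("feature_matrix", class(out)))
}

#' Full feature matrix for one query profile
#'
#' Standard composition used throughout: windowed profile scores,
#' optionally merged with a second windowed profile (e.g. the AA-PSSM) and
#' the amino-acid-type integer.
#'
#' @param profile An `sse_profile` (its `pssm` is windowed).
#' @param window_size Odd window width.
#' @param aa_profile Optional second `sse_profile` to merge (windowed the
#'   same way).
#' @param aa_type Include the amino-acid-type feature column?
#' @param extra Optional named list of additional per-residue matrices
#'   (e.g. imported external predictions), merged as-is.
#' @return A `feature_matrix` with one row per query residue.
#' @export
featurize_profile <- function(profile, window_size = 5L, aa_profile = NULL,
                              aa_type = TRUE, extra = NULL) {
  sources <- list(sse_pssm = window_features(profile$pssm, window_size))
  if (!is.null(aa_profile))
    sources$aa_pssm <- window_features(aa_profile$pssm, window_size)
  if (aa_type)
    sources$aa_type <- matrix(encode_amino_acid(profile$query),
                              ncol = 1, dimnames = list(NULL, "type"))
  if (!is.null(extra)) sources <- c(sources, extra)
  merge_features(sources)
}
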