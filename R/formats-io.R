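# Readers/writers for every format the pipeline touches. All user-facing
# coordinates are 1-based; sequences are stored as named character vectors
# (ids as names), the container seqinr/Biostrings users expect to flatten to.

#' Read amino-acid sequences from a FASTA file
#'
#' Sequences are upper-cased and trailing `*` terminators stripped. Legal
#' residue characters are the 20 standard amino acids plus `X` (unknown).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences; names are record ids (the
#'   first whitespace-delimited token of each header), in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate record id '", ids[anyDuplicated(ids)], "' in ", path,
         call. = FALSE)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs)))
    stop("empty sequence in record '", ids[!nzchar(seqs)][1], "'",
         call. = FALSE)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad))
    stop("non-amino-acid character in record '", ids[bad][1], "'",
         call. = FALSE)
  stats::setNames(seqs, ids)
}

#' Read SSE strings from a FASTA file
#'
#' Strings are upper-cased (with a warning) and validated against the
#' declared alphabet; an out-of-alphabet code is an error naming the record
#' and position.
#'
#' @param path Path to a FASTA file of SSE strings.
#' @param alphabet An [sse_alphabet()] or registered name.
#' @return Named character vector of SSE strings, in file order.
#' @export
read_sse_fasta <- function(path, alphabet) {
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  raw <- as.character(set)
  out <- vapply(seq_along(raw), function(i)
    validate_sse_string(raw[i], alphabet, id = ids[i]), character(1))
  stats::setNames(out, ids)
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector (ids as names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

.aln_header <- c("query_id", "hit_id", "query_aln", "hit_aln", "identity")

#' Read / write pairwise-alignment tables
#'
#' The alignment TSV dialect has a fixed five-column header
#' `query_id  hit_id  query_aln  hit_aln  identity`; `query_aln`/`hit_aln`
#' are gapped aligned strings of equal length and `identity` is a fraction
#' in `[0, 1]`. This is the injection point for alignments produced by
#' external search tools.
#'
#' @param path File path.
#' @return `read_alignment_tsv()` returns a `data.frame` with the five
#'   columns above (plus any extra numeric columns present, e.g. `score`
#'   and `q_start` written by [search_homologs()] output).
#' @export
read_alignment_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (!all(.aln_header %in% names(tab)))
    stop("alignment TSV must have header columns: ",
         paste(.aln_header, collapse = ", "), call. = FALSE)
  tab$identity <- as.numeric(tab$identity)
  for (extra in setdiff(names(tab), .aln_header))
    tab[[extra]] <- as.numeric(tab[[extra]])
  bad <- nchar(tab$query_aln) != nchar(tab$hit_aln)
  if (any(bad))
    stop("malformed row at line ", which(bad)[1] + 1L,
         ": aligned strings have unequal length", call. = FALSE)
  if (any(tab$identity < 0 | tab$identity > 1, na.rm = TRUE))
    stop("identity must be a fraction in [0, 1]", call. = FALSE)
  tab
}

#' @rdname read_alignment_tsv
#' @param table Alignment `data.frame` as returned by `read_alignment_tsv()`
#'   or [search_homologs()].
#' @export
write_alignment_tsv <- function(table, path) {
  stopifnot(all(.aln_header %in% names(table)))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write PSSM tables
#'
#' PSSMs are serialized as TSV with header `pos  res  <code1> ... <codeN>`;
#' `pos` is 1-based, `res` the query residue, and scores carry 4 decimal
#' places, so round trips are exact to 1e-4 per cell.
#'
#' @param profile An `sse_profile` (from [build_profile()]) or any object
#'   with elements `query` (residue string), `pssm` (matrix) and `alphabet`.
#' @param path File path.
#' @param what Which matrix of the profile to write (`"pssm"`, `"ppm"` or
#'   `"occ"`).
#' @return `read_pssm_tsv()` returns a list with elements `pssm`
#'   (positions x codes numeric matrix), `res` (residue characters) and
#'   `codes`.
#' @export
write_pssm_tsv <- function(profile, path, what = "pssm") {
  m <- profile[[what]]
  res <- strsplit(profile$query, "")[[1]]
  stopifnot(nrow(m) == length(res))
  tab <- data.frame(pos = seq_len(nrow(m)), res = res,
                    check.names = FALSE)
  for (j in seq_len(ncol(m))) tab[[colnames(m)[j]]] <- sprintf("%.4f", m[, j])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pssm_tsv
#' @param alphabet Optional [sse_alphabet()] (or name); when supplied, the
#'   file's score columns must match its codes exactly.
#' @export
read_pssm_tsv <- function(path, alphabet = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c(pos = "integer", res = "character"))
  if (!identical(names(tab)[1:2], c("pos", "res")))
    stop("PSSM TSV must start with columns 'pos' and 'res'", call. = FALSE)
  codes <- names(tab)[-(1:2)]
  if (!is.null(alphabet)) {
    if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
    if (!identical(codes, alphabet$codes))
      stop("PSSM columns (", paste(codes, collapse = ","),
           ") do not match alphabet '", alphabet$name, "' (",
           paste(alphabet$codes, collapse = ","), ")", call. = FALSE)
  }
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  list(pssm = m, res = tab$res, codes = codes)
}

#' Read / write SSE substitution matrices
#'
#' The text format mirrors the classic substitution-matrix layout: comment
#' header lines `# alphabet: <name>` and `# background: <code> <freq> ...`,
#' then a labeled square matrix with scores at 2 decimal places.
#'
#' @param sm An `sse_substitution_matrix` from [build_substitution_matrix()].
#' @param path File path.
#' @return `read_substitution_matrix()` returns an
#'   `sse_substitution_matrix`.
#' @export
write_substitution_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "sse_substitution_matrix"))
  codes <- sm$alphabet$codes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# alphabet: ", sm$alphabet$name), con)
  writeLines(paste0("# background: ",
                    paste(codes, sprintf("%.6f", sm$background[codes]),
                          collapse = " ")), con)
  writeLines(paste0("  ", paste(sprintf("%6s", codes), collapse = " ")), con)
  for (a in codes)
    writeLines(paste0(a, " ",
                      paste(sprintf("%6.2f", sm$scores[a, codes]),
                            collapse = " ")), con)
  invisible(path)
}

#' @rdname write_substitution_matrix
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  alpha_line <- grep("^# alphabet:", lines, value = TRUE)
  if (length(alpha_line) != 1L)
    stop("substitution-matrix file lacks '# alphabet:' header", call. = FALSE)
  alphabet <- sse_alphabet(trimws(sub("^# alphabet:", "", alpha_line)))
  bg <- NULL
  bg_line <- grep("^# background:", lines, value = TRUE)
  if (length(bg_line) == 1L) {
    toks <- strsplit(trimws(sub("^# background:", "", bg_line)), "\\s+")[[1]]
    bg <- stats::setNames(as.numeric(toks[c(FALSE, TRUE)]),
                          toks[c(TRUE, FALSE)])
  }
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  header <- strsplit(trimws(body[1]), "\\s+")[[1]]
  if (!setequal(header, alphabet$codes))
    stop("matrix column labels do not match alphabet '", alphabet$name, "'",
         call. = FALSE)
  k <- length(header)
  scores <- matrix(NA_real_, k, k, dimnames = list(header, header))
  for (line in body[-1]) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    scores[toks[1], header] <- as.numeric(toks[-1])
  }
  if (anyNA(scores)) stop("incomplete substitution matrix", call. = FALSE)
  scores <- scores[alphabet$codes, alphabet$codes]
  new_substitution_matrix(alphabet, scores, bg)
}
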