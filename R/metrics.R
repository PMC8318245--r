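# Evaluation suite: Q accuracy with macro (per-query) and micro
# (per-residue) averaging, the 1999-revision segment overlap measure (SOV),
# boundary/internal accuracy, and pairwise three-state misclassification
# rates.

.split1 <- function(s) strsplit(s, "")[[1]]

.check_pair <- function(actual, predicted) {
  if (nchar(actual) != nchar(predicted))
    stop("actual (", nchar(actual), ") and predicted (", nchar(predicted),
         ") strings have unequal length", call. = FALSE)
}

# Maximal same-code segments of an SSE string.
sse_segments <- function(s) {
  r <- rle(.split1(s))
  ends <- cumsum(r$lengths)
  data.frame(code = r$values, start = ends - r$lengths + 1L, end = ends,
             len = r$lengths, stringsAsFactors = FALSE)
}

#' Per-residue Q accuracy
#'
#' Fraction of residues whose predicted code equals the actual code.
#'
#' @param actual,predicted Equal-length SSE strings over one alphabet.
#' @return Fraction in `[0, 1]`.
#' @export
q_accuracy <- function(actual, predicted) {
  .check_pair(actual, predicted)
  mean(.split1(actual) == .split1(predicted))
}

#' Macro and micro averages of Q over queries
#'
#' The macro average (per-query mean) weights proteins equally regardless
#' of size; the micro average pools correctly predicted residues over all
#' queries and divides by the total residue count, weighting residues
#' equally. Supply either per-query `q_values` (correct counts are
#' recovered as `round(n * q)`) or exact `n_correct` counts.
#'
#' @param n_residues Integer vector of query lengths.
#' @param q_values Per-query Q accuracies (ignored when `n_correct`
#'   given).
#' @param n_correct Optional integer vector of correct-residue counts.
#' @return List with `macro`, `micro`, `n_correct_total`,
#'   `n_residues_total`.
#' @export
average_q <- function(n_residues, q_values = NULL, n_correct = NULL) {
  if (length(n_residues) == 0L) stop("no queries", call. = FALSE)
  stopifnot(all(n_residues >= 1))
  if (is.null(n_correct)) {
    stopifnot(!is.null(q_values), length(q_values) == length(n_residues))
    n_correct <- round(n_residues * q_values)
  }
  if (is.null(q_values)) q_values <- n_correct / n_residues
  list(macro = mean(q_values),
       micro = sum(n_correct) / sum(n_residues),
       n_correct_total = sum(n_correct),
       n_residues_total = sum(n_residues))
}

# SOV numerator and denominator (1999 revision), kept separate so pooled
# multi-query SOV can be computed residue-weighted.
sov_components <- function(actual, predicted) {
  .check_pair(actual, predicted)
  sa <- sse_segments(actual)
  sp <- sse_segments(predicted)
  num <- 0
  den <- 0
  for (st in unique(sa$code)) {
    s1s <- sa[sa$code == st, , drop = FALSE]
    s2s <- sp[sp$code == st, , drop = FALSE]
    for (i in seq_len(nrow(s1s))) {
      s1 <- s1s[i, ]
      overlapped <- FALSE
      for (j in seq_len(nrow(s2s))) {
        s2 <- s2s[j, ]
        minov <- min(s1$end, s2$end) - max(s1$start, s2$start) + 1L
        if (minov > 0L) {
          overlapped <- TRUE
          maxov <- max(s1$end, s2$end) - min(s1$start, s2$start) + 1L
          delta <- min(maxov - minov, minov, s1$len %/% 2L, s2$len %/% 2L)
          num <- num + (minov + delta) / maxov * s1$len
          den <- den + s1$len
        }
      }
      if (!overlapped) den <- den + s1$len
    }
  }
  c(num = num, den = den)
}

#' Segment overlap measure (SOV)
#'
#' The 1999 revision of the segment overlap score: for each state, every
#' overlapping pair of an actual segment s1 and predicted segment s2
#' contributes `(minov + delta) / maxov * len(s1)`, with
#' `delta = min(maxov - minov, minov, len(s1) %/% 2, len(s2) %/% 2)`; the
#' normalization sums `len(s1)` over all overlapping pairs plus all
#' non-overlapping actual segments. The same code path yields SOV3 on
#' three-state and SOV8 on eight-state strings. Unlike per-residue Q, SOV
#' rewards a correct segment pattern over exact boundary placement.
#'
#' @param actual,predicted Equal-length SSE strings.
#' @return Fraction (1 for identical strings).
#' @export
sov <- function(actual, predicted) {
  cmp <- sov_components(actual, predicted)
  unname(cmp["num"] / cmp["den"])
}

#' Boundary and internal accuracy
#'
#' Residues of the actual string are partitioned by the segment-terminus
#' rule: a residue is a boundary residue iff it is the first or last
#' residue of a maximal same-code segment of the actual string; all other
#' residues are internal. Per-partition match fractions are returned; an
#' empty partition yields `NaN` rather than a fabricated value.
#'
#' @param actual,predicted Equal-length SSE strings.
#' @return Named numeric `c(boundary = ..., internal = ...)`.
#' @export
boundary_internal_q <- function(actual, predicted) {
  .check_pair(actual, predicted)
  segs <- sse_segments(actual)
  boundary_idx <- unique(sort(c(segs$start, segs$end)))
  a <- .split1(actual)
  p <- .split1(predicted)
  internal_idx <- setdiff(seq_along(a), boundary_idx)
  c(boundary = if (length(boundary_idx))
      mean(a[boundary_idx] == p[boundary_idx]) else NaN,
    internal = if (length(internal_idx))
      mean(a[internal_idx] == p[internal_idx]) else NaN)
}

#' Pairwise three-state misclassification rates
#'
#' After reducing both strings to three states, the rate of confusing
#' states X and Y is the fraction of residues with (actual X, predicted Y)
#' or (actual Y, predicted X). The three pairwise rates plus the overall
#' Q3 sum to 1 exactly: every residue is either correct or exactly one
#' pair type.
#'
#' @param actual,predicted Equal-length SSE strings.
#' @param reduction [sse_reduction()] applied first; `NULL` when the
#'   strings are already three-state.
#' @return Named numeric `c("H<->E" = ..., "H<->C" = ..., "E<->C" = ...)`.
#' @export
misclassification_rates <- function(actual, predicted,
                                    reduction = sse_reduction("dssp8", "q3")) {
  .check_pair(actual, predicted)
  if (!is.null(reduction)) {
    actual <- reduce_sse(actual, reduction)
    predicted <- reduce_sse(predicted, reduction)
  }
  a <- .split1(actual)
  p <- .split1(predicted)
  n <- length(a)
  rate <- function(x, y) sum((a == x & p == y) | (a == y & p == x)) / n
  c("H<->E" = rate("H", "E"), "H<->C" = rate("H", "C"),
    "E<->C" = rate("E", "C"))
}

#' Evaluate predictions for a set of queries
#'
#' Computes the full metric suite per query and pooled over queries:
#' macro/micro Q, residue-weighted pooled SOV (summed SOV numerators over
#' summed denominators), pooled boundary/internal accuracy and pooled
#' three-state misclassification rates (all count-based), plus the pooled
#' confusion matrix.
#'
#' @param actual,predicted Named character vectors of equal-length SSE
#'   strings; names identify queries and must match.
#' @param alphabet [sse_alphabet()] or name of the strings' alphabet.
#' @param reduction Reduction used for misclassification rates; the
#'   identity is used automatically for three-state input.
#' @return An object of class `evaluation_report`: list with `per_query`
#'   (data frame), `macro_q`, `micro_q`, `sov`, `boundary_q`,
#'   `internal_q`, `misclassification`, `confusion`.
#' @export
evaluate_predictions <- function(actual, predicted, alphabet = "dssp8",
                                 reduction = NULL) {
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  if (is.null(names(actual)) || is.null(names(predicted)))
    stop("`actual` and `predicted` must be named by query id", call. = FALSE)
  if (!setequal(names(actual), names(predicted)))
    stop("query ids of `actual` and `predicted` differ", call. = FALSE)
  predicted <- predicted[names(actual)]
  if (is.null(reduction)) {
    reduction <- if (alphabet$name == "q3")
      sse_reduction("q3", "q3") else sse_reduction(alphabet$name, "q3")
  }
  codes <- alphabet$codes
  conf <- matrix(0L, length(codes), length(codes),
                 dimnames = list(actual = codes, predicted = codes))
  rows <- lapply(names(actual), function(id) {
    a <- actual[[id]]; p <- predicted[[id]]
    .check_pair(a, p)
    av <- .split1(a); pv <- .split1(p)
    conf <<- conf + table(factor(av, codes), factor(pv, codes))
    cmp <- sov_components(a, p)
    bi <- boundary_internal_q(a, p)
    data.frame(query_id = id, n_residues = nchar(a),
               n_correct = sum(av == pv), q = mean(av == pv),
               sov = unname(cmp["num"] / cmp["den"]),
               sov_num = unname(cmp["num"]), sov_den = unname(cmp["den"]),
               boundary_q = unname(bi["boundary"]),
               internal_q = unname(bi["internal"]),
               stringsAsFactors = FALSE)
  })
  per_query <- do.call(rbind, rows)
  # pooled boundary/internal and misclassification from counts
  bsum <- c(correct = 0, total = 0); isum <- c(correct = 0, total = 0)
  mis_counts <- c("H<->E" = 0, "H<->C" = 0, "E<->C" = 0)
  ntot <- 0
  for (id in names(actual)) {
    a <- actual[[id]]; p <- predicted[[id]]
    segs <- sse_segments(a)
    bidx <- unique(sort(c(segs$start, segs$end)))
    iidx <- setdiff(seq_len(nchar(a)), bidx)
    av <- .split1(a); pv <- .split1(p)
    bsum <- bsum + c(sum(av[bidx] == pv[bidx]), length(bidx))
    isum <- isum + c(sum(av[iidx] == pv[iidx]), length(iidx))
    mis_counts <- mis_counts +
      misclassification_rates(a, p, reduction) * nchar(a)
    ntot <- ntot + nchar(a)
  }
  avg <- average_q(per_query$n_residues, n_correct = per_query$n_correct)
  structure(list(
    per_query = per_query,
    macro_q = avg$macro,
    micro_q = avg$micro,
    sov = sum(per_query$sov_num) / sum(per_query$sov_den),
    boundary_q = if (bsum[2] > 0) bsum[1] / bsum[2] else NaN,
    internal_q = if (isum[2] > 0) isum[1] / isum[2] else NaN,
    misclassification = mis_counts / ntot,
    confusion = conf,
    alphabet = alphabet), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  k <- length(x$alphabet$codes)
  cat("Evaluation over ", nrow(x$per_query), " query/ies (",
      sum(x$per_query$n_residues), " residues, ", k, "-state):\n", sep = "")
  cat(sprintf("  Q%d  macro %.3f | micro %.3f\n", k, x$macro_q, x$micro_q))
  cat(sprintf("  SOV%d %.3f | boundary Q %.3f | internal Q %.3f\n",
              k, x$sov, x$boundary_q, x$internal_q))
  cat("  misclassification (3-state): ",
      paste(names(x$misclassification),
            sprintf("%.3f", x$misclassification), collapse = "  "), "\n",
      sep = "")
  invisible(x)
}
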