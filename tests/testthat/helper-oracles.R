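# Independent oracles, each written as the naive/brute-force counterpart
# of an implementation path and kept free of package internals.

# Exhaustive Gotoh local alignment (affine gaps), score only. A gap of
# length L costs gap_open + L * gap_extend.
oracle_local_score <- function(q, t, params) {
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(t, "")[[1]]
  n <- length(qs); m <- length(ts)
  sub <- function(a, b) {
    if (a == b && a != "X") params$match_score else params$mismatch_score
  }
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in t (consumes q)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in q (consumes t)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      diag_best <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1], 0)
      M[i, j] <- sub(qs[i - 1], ts[j - 1]) + diag_best
      Ix[i, j] <- max(M[i - 1, j] + params$gap_open + params$gap_extend,
                      Ix[i - 1, j] + params$gap_extend)
      Iy[i, j] <- max(M[i, j - 1] + params$gap_open + params$gap_extend,
                      Iy[i, j - 1] + params$gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Naive per-residue triple-loop occurrence recount from raw alignment rows
# (query_aln / sse_aln strings plus weights and query-start offsets).
oracle_occurrences <- function(query_len, rows, codes) {
  occ <- matrix(0, query_len, length(codes), dimnames = list(NULL, codes))
  for (r in rows) {
    q <- strsplit(r$query_aln, "")[[1]]
    s <- strsplit(r$sse_aln, "")[[1]]
    qpos <- r$q_start - 1L
    for (i in seq_along(q)) {
      if (q[i] != "-") {
        qpos <- qpos + 1L
        if (s[i] != "-" && s[i] %in% codes)
          occ[qpos, s[i]] <- occ[qpos, s[i]] + r$weight
      }
    }
  }
  occ
}

# Hand pair-counting BLOSUM oracle: unordered pair counts over gap-free
# columns, marginals, expected frequencies, log2 odds.
oracle_blosum <- function(pairs, codes, floor = -10) {
  counts <- matrix(0, length(codes), length(codes),
                   dimnames = list(codes, codes))
  for (pr in pairs) {
    a <- strsplit(pr[[1]], "")[[1]]
    b <- strsplit(pr[[2]], "")[[1]]
    for (i in seq_along(a)) {
      if (a[i] != "-" && b[i] != "-") {
        counts[a[i], b[i]] <- counts[a[i], b[i]] + 1
        if (a[i] != b[i]) counts[b[i], a[i]] <- counts[b[i], a[i]] + 1
      }
    }
  }
  # each unordered pair counted once: off-diagonal cells hold the full
  # unordered count in both mirror positions
  total <- (sum(counts) + sum(diag(counts))) / 2
  q <- counts / total
  p <- numeric(length(codes)); names(p) <- codes
  for (a in codes) p[a] <- q[a, a] + sum(q[a, setdiff(codes, a)]) / 2
  scores <- matrix(floor, length(codes), length(codes),
                   dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    e <- if (a == b) p[a]^2 else 2 * p[a] * p[b]
    if (q[a, b] > 0 && e > 0) scores[a, b] <- log2(q[a, b] / e)
  }
  scores
}

# random SSE string over given codes
random_sse <- function(n, codes) paste(sample(codes, n, replace = TRUE),
                                       collapse = "")

# random amino-acid string
random_aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                               "")[[1]],
                                      n, replace = TRUE), collapse = "")

# a tiny 3-state substitution matrix built from a fixed toy corpus; used
# wherever tests need *some* valid sse_substitution_matrix
toy_subst_q3 <- function() {
  build_substitution_matrix(
    list(c("HHHEEECCC", "HHHEEECCC"),
         c("HHEECCHHC", "HHHECCCHC"),
         c("CCHHHEEEC", "CCHHHEECC")),
    "q3")
}
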