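test_that("SSE transformation threads codes through the gap structure", {
  tr <- transform_alignment("ILKGWAAL", "IL-GW--L", "CHHEE", 1,
                            hit_sequence = "ILGWL")
  expect_identical(tr$sse_aln, "CH-HE--E")
  # all-gap hit side stays all gaps
  expect_identical(
    transform_alignment("MKVLI", "-----", "CHHEE", 0.5)$sse_aln, "-----")
  # SSE shorter than the hit sequence -> length-mismatch error
  expect_error(
    transform_alignment("ILKGWAAL", "IL-GW--L", "CHHE", 1,
                        hit_sequence = "ILGWL"),
    "length mismatch")
  expect_error(
    transform_alignment("ILKGWAAL", "IL-GW--L", "CHHE", 1),
    "length mismatch")
})

test_that("transformation respects local-alignment offsets", {
  # aligned region covers hit residues 3..7 of a 9-residue hit
  tr <- transform_alignment("GWLAF", "GWLAF", "CCHHEEECC", 1,
                            hit_start = 3L)
  expect_identical(tr$sse_aln, "HHEEE")
})

test_that("occurrences implement the weighted indicator sum", {
  a <- sse_alphabet("q3")
  tr1 <- transform_alignment("MKV", "IKV", "HHH", 1.0, q_start = 1L)
  occ <- compute_occurrences("MKV", list(tr1), a)
  expect_equal(unname(occ[1, ]), c(1, 0, 0))
  # linearity: two hits with weights 0.8 and 0.4, both C at p1 -> 1.2
  tr2 <- transform_alignment("M", "C", "C", 0.8, q_start = 1L)
  tr3 <- transform_alignment("M", "A", "C", 0.4, q_start = 1L)
  occ <- compute_occurrences("MKV", list(tr2, tr3), a)
  expect_equal(unname(occ[1, "C"]), 1.2)
  expect_equal(sum(occ[2:3, ]), 0)
})

test_that("occurrence matrix equals the naive triple-loop oracle", {
  a <- sse_alphabet("dssp8")
  set.seed(13)
  for (rep in 1:8) {
    qlen <- sample(3:10, 1)
    n_hits <- sample(1:5, 1)
    rows <- lapply(seq_len(n_hits), function(i) {
      alen <- sample(2:qlen, 1)
      q_start <- sample(seq_len(qlen - alen + 1), 1)
      # build aligned strings with random gaps on both sides
      q <- character(0); s <- character(0); qleft <- alen
      while (qleft > 0) {
        kind <- sample(c("m", "gq", "gh"), 1, prob = c(0.7, 0.15, 0.15))
        if (kind == "gq") { q <- c(q, "-"); s <- c(s, sample(a$codes, 1)) }
        else if (kind == "gh") { q <- c(q, "A"); s <- c(s, "-"); qleft <- qleft - 1 }
        else { q <- c(q, "A"); s <- c(s, sample(a$codes, 1)); qleft <- qleft - 1 }
      }
      list(query_aln = paste(q, collapse = ""),
           sse_aln = paste(s, collapse = ""),
           weight = round(runif(1), 2), q_start = q_start)
    })
    trs <- lapply(rows, function(r)
      structure(r, class = "transformed_alignment"))
    got <- compute_occurrences(qlen, trs, a)
    expect_equal(unclass(got), oracle_occurrences(qlen, rows, a$codes),
                 ignore_attr = TRUE)
  }
})

test_that("occurrences beyond the query length are an index error", {
  tr <- transform_alignment("MKVL", "HKVL", "HHHH", 1, q_start = 2L)
  expect_error(compute_occurrences("MKVL", list(tr), sse_alphabet("q3"),
                                   unknown_action = "skip"),
               "beyond query length")
})

test_that("PPM normalizes occurrence rows and records fallbacks", {
  occ <- structure(matrix(c(3, 1, 0,
                            0, 0, 0), 2, 3, byrow = TRUE,
                          dimnames = list(NULL, c("H", "E", "C"))),
                   class = "occurrence_matrix")
  bg <- compute_background(c(x = "HHEC"), "q3")
  res <- ppm_from_occurrences(occ, bg)
  expect_equal(unname(res$ppm[1, ]), c(0.75, 0.25, 0))
  expect_equal(res$ppm[2, ], unclass(bg), ignore_attr = TRUE)
  expect_identical(res$pseudocount_positions, 2L)
  expect_equal(rowSums(res$ppm), c(1, 1), ignore_attr = TRUE)
})

test_that("pseudocount mixture matches the stated formula by hand", {
  sm <- toy_subst_q3()
  bg <- structure(c(H = 0.4, E = 0.3, C = 0.3), class = "background_freqs")
  occ_col <- c(H = 2, E = 0, C = 0)

  # tau = 0: frequencies unchanged
  expect_equal(apply_pseudocounts(occ_col, bg, sm, tau = 0),
               c(H = 1, E = 0, C = 0))
  # N_p = 0: background fallback for any tau
  expect_equal(apply_pseudocounts(c(H = 0, E = 0, C = 0), bg, sm, 1),
               unclass(bg), ignore_attr = TRUE)
  expect_error(apply_pseudocounts(occ_col, bg, sm, tau = -1), "tau")

  # hand computation: recover T from the matrix definition independently
  codes <- c("H", "E", "C")
  p <- sm$background[codes]
  e <- 2 * outer(p, p); diag(e) <- p^2
  qm <- e * 2^sm$scores[codes, codes]
  joint <- qm
  joint[row(joint) != col(joint)] <- joint[row(joint) != col(joint)] / 2
  joint <- joint / sum(joint)
  tmat <- sweep(joint, 2, colSums(joint), "/")
  f <- occ_col / sum(occ_col)
  g <- as.numeric(tmat %*% f)
  expected <- (2 * f + 1 * g) / (2 + 1)
  expected <- expected / sum(expected)
  got <- apply_pseudocounts(occ_col, bg, sm, tau = 1)
  expect_equal(unname(got), unname(expected), tolerance = 1e-12)
  expect_equal(sum(got), 1)
  expect_true(all(got > 0))
})

test_that("PSSM is the log2 odds with a floor at zero cells", {
  bg <- structure(c(H = 0.25, E = 0.25, C = 0.5),
                  class = "background_freqs")
  ppm <- matrix(c(0.5, 0.5, 0,
                  0.25, 0.25, 0.5), 2, 3, byrow = TRUE,
                dimnames = list(NULL, c("H", "E", "C")))
  pssm <- pssm_from_ppm(ppm, bg)
  expect_equal(unname(pssm[1, "H"]), 1)          # log2(0.5 / 0.25)
  expect_equal(unname(pssm[1, "C"]), -10)        # floor
  expect_equal(unname(pssm[2, ]), c(0, 0, 0))  # PPM == background
  expect_error(pssm_from_ppm(ppm, c(H = 0.5, E = 0.5, C = 0)),
               "strictly positive")
})

test_that("a single gapless full-identity hit gives a one-hot PPM", {
  hits <- data.frame(query_id = "q", hit_id = "h",
                     query_aln = "MKVLI", hit_aln = "MKVLI",
                     identity = 1, q_start = 1L, h_start = 1L,
                     stringsAsFactors = FALSE)
  bg <- compute_background(c(h = "CHHEC"), "q3")
  prof <- build_profile(c(q = "MKVLI"), hits, c(h = "CHHEC"), "q3", bg,
                        tau = 0)
  onehot <- import_external_prediction("CHHEC", "q3")
  expect_equal(prof$ppm, unclass(onehot), ignore_attr = TRUE)
  expect_length(prof$pseudocount_positions, 0)
})

test_that("zero hits fall back to background everywhere with zero PSSM", {
  hits <- data.frame(query_id = character(0), hit_id = character(0),
                     query_aln = character(0), hit_aln = character(0),
                     identity = numeric(0), stringsAsFactors = FALSE)
  bg <- compute_background(c(h = "CHHECCEH"), "q3")
  prof <- build_profile(c(q = "MKVLI"), hits, character(0), "q3", bg,
                        tau = 0)
  expect_identical(prof$pseudocount_positions, 1:5)
  for (i in 1:5) expect_equal(prof$ppm[i, ], unclass(bg),
                              ignore_attr = TRUE)
  expect_true(all(prof$pssm == 0))
})

test_that("profiles are invariant to hit order and conserve weight mass", {
  fam <- generate_family(family_params(seed = 21, alphabet = "dssp8"))
  q <- stats::setNames(fam$query$seq, fam$query$id)
  hits <- search_homologs(q, fam$targets)
  bg <- compute_background(fam$target_sse, "dssp8")
  p1 <- build_profile(q, hits, fam$target_sse, "dssp8", bg, tau = 0)
  p2 <- build_profile(q, hits[rev(seq_len(nrow(hits))), ], fam$target_sse,
                      "dssp8", bg, tau = 0)
  expect_equal(p1$ppm, p2$ppm)
  # conservation: row mass equals summed weights of hits covering p
  n <- nchar(fam$query$seq)
  covered <- matrix(0, n, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    qc <- strsplit(hits$query_aln[i], "")[[1]]
    hc <- strsplit(hits$hit_aln[i], "")[[1]]
    qpos <- hits$q_start[i] - 1L
    for (j in seq_along(qc)) {
      if (qc[j] != "-") {
        qpos <- qpos + 1L
        if (hc[j] != "-") covered[qpos, i] <- hits$identity[i]
      }
    }
  }
  expect_equal(unname(rowSums(p1$occ)), unname(rowSums(covered)),
               tolerance = 1e-12)
})

test_that("dssp8 profile mass reduced to q3 equals the q3-built profile", {
  fam <- generate_family(family_params(seed = 8, alphabet = "dssp8"))
  q <- stats::setNames(fam$query$seq, fam$query$id)
  hits <- search_homologs(q, fam$targets)
  bg8 <- compute_background(fam$target_sse, "dssp8")
  p8 <- build_profile(q, hits, fam$target_sse, "dssp8", bg8, tau = 0)
  red <- sse_reduction("dssp8", "q3")
  sse3 <- reduce_sse(fam$target_sse, red) |>
    stats::setNames(names(fam$target_sse))
  bg3 <- compute_background(sse3, "q3")
  p3 <- build_profile(q, hits, sse3, "q3", bg3, tau = 0)
  mass <- sapply(sse_alphabet("q3")$codes, function(tc)
    rowSums(p8$ppm[, names(red$mapping)[red$mapping == tc], drop = FALSE]))
  expect_equal(unname(mass), unname(p3$ppm), tolerance = 1e-12)
})

test_that("background frequencies count codes with add-one smoothing", {
  bg <- compute_background(c(a = "HHEE"), "q3")
  # C absent -> counts (2, 2, 0) + 1 each = (3, 3, 1) over 7
  expect_equal(unclass(bg), c(H = 3 / 7, E = 3 / 7, C = 1 / 7))
  expect_equal(sum(bg), 1)
  expect_error(compute_background(character(0), "q3"), "empty")
  # pooled count equals a per-string loop oracle
  lib <- c(a = "HHECC", b = "EEC", c = "HCC")
  counts <- c(H = 0, E = 0, C = 0)
  for (s in lib) for (ch in strsplit(s, "")[[1]])
    counts[ch] <- counts[ch] + 1
  expect_equal(unclass(compute_background(lib, "q3")),
               counts / sum(counts))
})

test_that("substitution matrix matches hand pair-counting on a toy corpus", {
  pairs <- list(c("HHEC", "HECC"), c("HE-C", "HHEC"))
  sm <- build_substitution_matrix(pairs, "q3")
  oracle <- oracle_blosum(pairs, c("H", "E", "C"))
  expect_equal(sm$scores, oracle, tolerance = 1e-12)
  expect_identical(sm$scores, t(sm$scores))
})

test_that("substitution matrix is symmetric on random corpora", {
  set.seed(3)
  for (rep in 1:5) {
    pairs <- lapply(1:4, function(i)
      c(random_sse(20, c("H", "E", "C")), random_sse(20, c("H", "E", "C"))))
    sm <- build_substitution_matrix(pairs, "q3")
    expect_identical(sm$scores, t(sm$scores))
    expect_equal(sm$scores, oracle_blosum(pairs, c("H", "E", "C")),
                 tolerance = 1e-12)
  }
})

test_that("identical-string corpora put all mass on the diagonal", {
  sm <- build_substitution_matrix(list(c("HHEECC", "HHEECC")), "q3")
  off <- sm$scores[row(sm$scores) != col(sm$scores)]
  expect_true(all(off == -10))
  expect_true(all(diag(sm$scores) > 0))
  expect_error(build_substitution_matrix(list(c("--", "--")), "q3"),
               "no usable")
})
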