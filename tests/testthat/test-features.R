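test_that("window of 1 is the identity and padding fills the edges", {
  m <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  w1 <- window_features(m, 1)
  expect_equal(unclass(w1), m, ignore_attr = TRUE)

  # 3-residue protein, window 5, 8 columns -> 40 features; residue 1 has
  # the two leftmost window offsets (16 cells) padded
  m8 <- matrix(rnorm(24), 3, 8)
  w5 <- window_features(m8, 5, pad_value = 0)
  expect_identical(dim(w5), c(3L, 40L))
  expect_true(all(w5[1, 1:16] == 0))
  expect_error(window_features(m8, 4), "odd")
})

test_that("windowed rows equal a naive slice oracle", {
  set.seed(19)
  m <- matrix(rnorm(60), 12, 5)
  colnames(m) <- paste0("c", 1:5)
  w <- window_features(m, 5, pad_value = -1)
  k <- 2L
  for (p in seq_len(nrow(m))) {
    expected <- unlist(lapply((p - k):(p + k), function(i)
      if (i >= 1 && i <= nrow(m)) m[i, ] else rep(-1, ncol(m))))
    expect_equal(unname(w[p, ]), unname(expected))
  }
})

test_that("amino-acid encoding is a bijection with X as sentinel", {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  codes <- encode_amino_acid(aas)
  expect_setequal(codes, 1:20)
  expect_identical(encode_amino_acid("X"), 0L)
  expect_error(encode_amino_acid("Z"), "invalid residue")
  # string input splits into residues
  expect_identical(encode_amino_acid("AXA"),
                   c(encode_amino_acid("A"), 0L, encode_amino_acid("A")))
})

test_that("encoding order follows class hydropathy then abundance", {
  tab <- amino_acid_encoding()
  # recompute the ordering from the table's own columns (oracle route)
  class_means <- tapply(tab$hydropathy, tab$class, mean)
  expected_classes <- names(sort(class_means, decreasing = TRUE))
  expect_identical(unique(tab$class), expected_classes)
  for (cl in expected_classes) {
    sub <- tab[tab$class == cl, ]
    # same-class residues occupy a consecutive integer block
    expect_identical(sub$code, seq(min(sub$code), max(sub$code)))
    expect_true(all(diff(sub$abundance) > 0))
  }
})

test_that("feature merging concatenates columns with source prefixes", {
  a <- matrix(1, 4, 2, dimnames = list(NULL, c("x", "y")))
  b <- matrix(2, 4, 3, dimnames = list(NULL, c("u", "v", "w")))
  merged <- merge_features(list(sse = a, aa = b))
  expect_identical(colnames(merged),
                   c("sse.x", "sse.y", "aa.u", "aa.v", "aa.w"))
  expect_identical(dim(merged), c(4L, 5L))
  # single source is (a prefixed) identity
  one <- merge_features(list(only = a))
  expect_equal(unclass(one), a, ignore_attr = TRUE)
  expect_error(merge_features(list(a, matrix(0, 3, 1))), "differing")
})

test_that("the standard feature merge has the documented width", {
  # SSE-PSSM (8 cols, w=5) + AA-PSSM (20 cols, w=5) + aa-type = 141
  sse <- matrix(0, 6, 8)
  aa <- matrix(0, 6, 20)
  merged <- merge_features(list(
    sse_pssm = window_features(sse, 5),
    aa_pssm = window_features(aa, 5),
    aa_type = matrix(0, 6, 1, dimnames = list(NULL, "type"))))
  expect_identical(ncol(merged), 141L)
})

test_that("windowing and merging commute up to column permutation", {
  set.seed(23)
  a <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("a", 1:4)))
  b <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("b", 1:3)))
  wm <- window_features(merge_features(list(A = a, B = b)), 5)
  mw <- merge_features(list(A = window_features(a, 5),
                            B = window_features(b, 5)))
  # same multiset of (name-derived) columns, same values
  key_wm <- sub("^(A|B)\\.", "\\1_", colnames(wm))
  key_mw <- vapply(strsplit(colnames(mw), "\\."), function(x)
    paste0(x[1], "_", x[2], ".", x[3]), character(1))
  expect_setequal(key_wm, key_mw)
  expect_equal(wm[, order(key_wm)], mw[, order(key_mw)],
               ignore_attr = TRUE)
})

test_that("external predictions import as one-hot or renormalized rows", {
  onehot <- import_external_prediction("H", "q3")
  expect_equal(unclass(onehot),
               matrix(c(1, 0, 0), 1, dimnames = list(NULL, c("H", "E", "C"))),
               ignore_attr = TRUE)
  expect_identical(colnames(onehot), c("H", "E", "C"))

  rows <- matrix(c(0.5, 0.3, 0.2,
                   0.3335, 0.3335, 0.333), 2, 3, byrow = TRUE)
  ok <- import_external_prediction(rows, "q3")
  expect_equal(rowSums(ok), c(1, 1))
  expect_equal(ok[1, ], c(H = 0.5, E = 0.3, C = 0.2))

  expect_error(import_external_prediction(matrix(c(0.5, 0.2, 0.2), 1),
                                          "q3"),
               "malformed probabilities")
  expect_error(import_external_prediction("Z", "q3"), "not a code")
  expect_error(import_external_prediction(matrix(0.5, 1, 2), "q3"),
               "3 columns")
})
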