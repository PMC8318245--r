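# separable synthetic features: class fully determined by one column
make_separable <- function(n, seed = 1) {
  set.seed(seed)
  labels <- sample(c("H", "E", "C"), n, replace = TRUE)
  signal <- c(H = -3, E = 0, C = 3)[labels]
  x <- cbind(signal + rnorm(n, sd = 0.1), matrix(rnorm(3 * n), n, 3))
  colnames(x) <- paste0("f", 1:4)
  list(x = x, labels = labels)
}

test_that("fits are deterministic given the seed", {
  d <- make_separable(150)
  p <- ensemble_params(n_members = 8, seed = 42, alphabet = "q3")
  m1 <- fit_sse_ensemble(d$x, d$labels, p)
  m2 <- fit_sse_ensemble(d$x, d$labels, p)
  probe <- make_separable(40, seed = 2)
  expect_identical(predict_proba(m1, probe$x), predict_proba(m2, probe$x))
  expect_identical(predict_sse(m1, probe$x), predict_sse(m2, probe$x))
})

test_that("probabilities are vote fractions summing to one", {
  d <- make_separable(120)
  for (kind in c("tree", "mixed")) {
    p <- ensemble_params(n_members = 10, member_kind = kind, seed = 7,
                         alphabet = "q3",
                         feature_fraction = 0.75)
    m <- fit_sse_ensemble(d$x, d$labels, p)
    probe <- make_separable(30, seed = 3)
    pr <- predict_proba(m, probe$x)
    expect_equal(unname(rowSums(pr)), rep(1, 30))
    expect_true(all(abs(pr * 10 - round(pr * 10)) < 1e-9))
  }
})

test_that("planted signal is learned to high training accuracy", {
  d <- make_separable(300, seed = 9)
  m <- fit_sse_ensemble(d$x, d$labels,
                        ensemble_params(n_members = 10, seed = 5,
                                        alphabet = "q3"))
  pred <- strsplit(predict_sse(m, d$x), "")[[1]]
  expect_gte(mean(pred == d$labels), 0.95)
})

test_that("a degenerate ensemble equals a single plain classifier", {
  d <- make_separable(200, seed = 4)
  p <- ensemble_params(n_members = 1, bootstrap_fraction = 1,
                       feature_fraction = 1, seed = 11, alphabet = "q3")
  m <- fit_sse_ensemble(d$x, d$labels, p)
  probe <- make_separable(50, seed = 6)
  pr <- predict_proba(m, probe$x)
  # single member: every probability row is one-hot
  expect_true(all(pr %in% c(0, 1)))
  # and equals the same rpart fit on the member's own bootstrap sample
  set.seed(ssepssm:::.member_seed(p, 1L))
  rows <- sample.int(200, 200, replace = TRUE)
  df <- as.data.frame(d$x[rows, ]); names(df) <- paste0("f", 1:4)
  df$.label <- droplevels(factor(d$labels[rows], c("H", "E", "C")))
  ref <- rpart::rpart(.label ~ ., df, method = "class",
                      control = rpart::rpart.control(xval = 0, cp = 0.002,
                                                     minsplit = 10))
  probe_df <- as.data.frame(probe$x); names(probe_df) <- paste0("f", 1:4)
  ref_pred <- as.character(predict(ref, probe_df, type = "class"))
  expect_identical(strsplit(predict_sse(m, probe$x), "")[[1]], ref_pred)
})

test_that("argmax of probabilities is the majority vote string", {
  d <- make_separable(150, seed = 8)
  m <- fit_sse_ensemble(d$x, d$labels,
                        ensemble_params(n_members = 9, seed = 3,
                                        alphabet = "q3",
                                        bootstrap_fraction = 0.5))
  probe <- make_separable(40, seed = 10)
  pr <- predict_proba(m, probe$x)
  codes <- c("H", "E", "C")
  manual <- codes[apply(pr, 1, which.max)]
  expect_identical(strsplit(predict_sse(m, probe$x), "")[[1]], manual)
})

test_that("degenerate inputs are rejected or handled", {
  d <- make_separable(50)
  expect_error(
    fit_sse_ensemble(d$x, rep("H", 50),
                     ensemble_params(alphabet = "q3")),
    "degenerate training set")
  m <- fit_sse_ensemble(d$x, d$labels,
                        ensemble_params(n_members = 3, seed = 1,
                                        alphabet = "q3"))
  expect_identical(predict_sse(m, d$x[0, , drop = FALSE]), "")
  expect_error(predict_proba(m, d$x[, 1:2]), "feature mismatch")
  expect_error(
    fit_sse_ensemble(d$x, sub("C", "Z", d$labels),
                     ensemble_params(alphabet = "q3")),
    "outside alphabet")
})

test_that("8-state predictions reduce consistently", {
  # reduction of predict_sse output equals predicting then reducing
  set.seed(15)
  labels8 <- sample(sse_alphabet("dssp8")$codes, 200, replace = TRUE,
                    prob = c(1, 4, 1, 3, 1, 2, 2, 4))
  signal <- as.numeric(factor(labels8, sse_alphabet("dssp8")$codes))
  x <- cbind(signal + rnorm(200, sd = 0.05), rnorm(200))
  colnames(x) <- c("f1", "f2")
  m <- fit_sse_ensemble(x, labels8,
                        ensemble_params(n_members = 5, seed = 2,
                                        alphabet = "dssp8"))
  pred8 <- predict_sse(m, x)
  expect_identical(nchar(pred8), 200L)
  # reducing the 8-state prediction gives a valid 3-state string whose
  # per-residue codes are the reduced argmax codes
  pred3 <- reduce_sse(pred8)
  codes8 <- sse_alphabet("dssp8")$codes
  pr <- predict_proba(m, x)
  argmax <- codes8[apply(pr, 1, which.max)]
  expect_identical(strsplit(pred3, "")[[1]],
                   unname(reduce_sse(argmax)))
})
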