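# Bootstrap-vote ensemble of per-residue classifiers. Each member is
# trained on a seeded bootstrap of the residues and a seeded subset of the
# features; class probabilities are the fractions of member votes, so a
# prediction's confidence is directly the agreement of the ensemble.

#' Ensemble parameters
#'
#' Defaults use 20 decision-tree members, a configuration small enough for
#' routine runs; the 100-member mixed configuration (50 trees + 50 neural
#' networks) is reachable with `n_members = 100, member_kind = "mixed"`.
#'
#' @param n_members Number of ensemble members (>= 1).
#' @param member_kind `"tree"` (rpart decision trees), `"mlp"`
#'   (single-hidden-layer nnet networks), or `"mixed"` (half and half).
#' @param bootstrap_fraction Fraction of residues drawn (with replacement)
#'   per member, in (0, 1].
#' @param feature_fraction Fraction of feature columns per member, in
#'   (0, 1].
#' @param seed Master seed; member m derives its own seed from it, so fits
#'   are reproducible.
#' @param alphabet [sse_alphabet()] or name; the prediction label set.
#' @param hidden_units Hidden-layer size for `"mlp"` members.
#' @return A list of class `ensemble_params`.
#' @export
ensemble_params <- function(n_members = 20L, member_kind = "tree",
                            bootstrap_fraction = 1, feature_fraction = 0.7,
                            seed = 1L, alphabet = "dssp8",
                            hidden_units = 8L) {
  member_kind <- match.arg(member_kind, c("tree", "mlp", "mixed"))
  stopifnot(n_members >= 1, bootstrap_fraction > 0, bootstrap_fraction <= 1,
            feature_fraction > 0, feature_fraction <= 1)
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  structure(list(n_members = as.integer(n_members),
                 member_kind = member_kind,
                 bootstrap_fraction = bootstrap_fraction,
                 feature_fraction = feature_fraction,
                 seed = as.integer(seed), alphabet = alphabet,
                 hidden_units = as.integer(hidden_units)),
            class = "ensemble_params")
}

.member_seed <- function(params, m) (params$seed %% 1000000L) * 1000L + m

.fit_member <- function(kind, x, y, params) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.label <- y
  if (kind == "tree") {
    rpart::rpart(.label ~ ., data = df, method = "class",
                 control = rpart::rpart.control(xval = 0, cp = 0.002,
                                                minsplit = 10))
  } else {
    nnet::nnet(.label ~ ., data = df, size = params$hidden_units,
               maxit = 120, decay = 0.01, trace = FALSE,
               MaxNWts = 50000)
  }
}

.predict_member <- function(member, kind, x, levels) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  if (kind == "tree") {
    p <- predict(member, newdata = df, type = "class")
    as.character(p)
  } else {
    as.character(predict(member, newdata = df, type = "class"))
  }
}

#' Fit a bootstrap-vote ensemble
#'
#' Trains `n_members` per-residue classifiers, each on its own seeded
#' bootstrap sample of rows and seeded subset of feature columns. The fit
#' is deterministic given `params$seed`.
#'
#' @param features Numeric feature matrix (residues stacked over training
#'   queries x features), e.g. from [featurize_profile()].
#' @param labels Character vector of SSE codes, one per row of `features`.
#' @param params An [ensemble_params()].
#' @return An object of class `sse_ensemble`.
#' @export
fit_sse_ensemble <- function(features, labels, params = ensemble_params()) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  codes <- params$alphabet$codes
  bad <- setdiff(unique(labels), codes)
  if (length(bad))
    stop("label(s) outside alphabet '", params$alphabet$name, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("degenerate training set: all labels are '", labels[1], "'",
         call. = FALSE)
  y <- factor(labels, levels = codes)
  n <- nrow(features)
  k <- ncol(features)
  kinds <- switch(params$member_kind,
    tree = rep("tree", params$n_members),
    mlp = rep("mlp", params$n_members),
    mixed = rep(c("tree", "mlp"), length.out = params$n_members))
  members <- vector("list", params$n_members)
  feat_idx <- vector("list", params$n_members)
  for (m in seq_len(params$n_members)) {
    set.seed(.member_seed(params, m))
    rows <- sample.int(n, size = max(2L, round(params$bootstrap_fraction * n)),
                       replace = TRUE)
    # resample until the bootstrap carries >= 2 classes
    tries <- 0L
    while (length(unique(y[rows])) < 2L && tries < 20L) {
      rows <- sample.int(n, size = length(rows), replace = TRUE)
      tries <- tries + 1L
    }
    cols <- sort(sample.int(k, size = max(1L,
                                          ceiling(params$feature_fraction * k))))
    members[[m]] <- .fit_member(kinds[m], features[rows, cols, drop = FALSE],
                                droplevels(y[rows]), params)
    feat_idx[[m]] <- cols
  }
  structure(list(members = members, member_kinds = kinds,
                 feature_idx = feat_idx, params = params,
                 feature_names = colnames(features),
                 n_features = k),
            class = "sse_ensemble")
}

#' @export
print.sse_ensemble <- function(x, ...) {
  cat("SSE ensemble: ", x$params$n_members, " ", x$params$member_kind,
      " member(s) over ", x$n_features, " features, alphabet '",
      x$params$alphabet$name, "'\n", sep = "")
  invisible(x)
}

#' Per-residue class probabilities as vote fractions
#'
#' Each member casts one vote per residue; the probability of code c is
#' the fraction of members voting c, so every entry is a multiple of
#' `1 / n_members` and rows sum to 1.
#'
#' @param model An `sse_ensemble`.
#' @param features Feature matrix with the same columns as at training.
#' @return Numeric matrix, residues x alphabet codes.
#' @export
predict_proba <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop("feature mismatch: model was trained on ", model$n_features,
         " features, got ", ncol(features), call. = FALSE)
  codes <- model$params$alphabet$codes
  n <- nrow(features)
  votes <- matrix(0L, n, length(codes), dimnames = list(NULL, codes))
  if (n == 0L) return(votes)
  for (m in seq_along(model$members)) {
    x <- features[, model$feature_idx[[m]], drop = FALSE]
    pred <- .predict_member(model$members[[m]], model$member_kinds[m], x,
                            codes)
    j <- match(pred, codes)
    votes[cbind(seq_len(n), j)] <- votes[cbind(seq_len(n), j)] + 1L
  }
  votes / length(model$members)
}

#' Predict an SSE string
#'
#' Argmax of the vote-fraction probabilities; ties go to the earliest code
#' in the alphabet order.
#'
#' @inheritParams predict_proba
#' @return A single SSE string (empty for an empty feature matrix).
#' @export
predict_sse <- function(model, features) {
  p <- predict_proba(model, features)
  if (nrow(p) == 0L) return("")
  codes <- model$params$alphabet$codes
  paste(codes[apply(p, 1, which.max)], collapse = "")
}
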