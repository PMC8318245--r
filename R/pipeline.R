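# End-to-end convenience layer: one call from a query plus an annotated
# target set to per-residue features, and one call from a generated
# benchmark to an evaluation report.

#' Search a query and build its profile features
#'
#' Runs the homolog search, builds the SSE profile (and optionally the
#' amino-acid profile over the same machinery), and windows the PSSM(s)
#' into a per-residue feature matrix.
#'
#' @param query Single named character (query sequence).
#' @param targets Named character vector of target sequences.
#' @param target_sse Named character vector of the targets' SSE strings.
#' @param alphabet [sse_alphabet()] or name of the SSE strings.
#' @param background Precomputed [compute_background()]; computed from
#'   `target_sse` when `NULL`.
#' @param subst Substitution matrix for pseudocounts (needed when
#'   `tau > 0`).
#' @param tau Pseudocount mass.
#' @param window_size Odd window width for [window_features()].
#' @param feature_set `"sse"` (SSE-PSSM features), `"aa"` (classic
#'   AA-PSSM features) or `"both"` (merged).
#' @param aa_type Append the amino-acid-type integer feature?
#' @param params [search_params()] for the hit search.
#' @return List with `features` (a `feature_matrix`), `profile`
#'   (`sse_profile` or `NULL`), `aa_profile`, `hits`.
#' @export
query_features <- function(query, targets, target_sse, alphabet = "dssp8",
                           background = NULL, subst = NULL, tau = 0.5,
                           window_size = 5L,
                           feature_set = c("sse", "aa", "both"),
                           aa_type = TRUE, params = search_params()) {
  feature_set <- match.arg(feature_set)
  if (is.character(alphabet)) alphabet <- sse_alphabet(alphabet)
  hits <- search_homologs(query, targets, params)
  sources <- list()
  profile <- NULL
  aa_profile <- NULL
  if (feature_set %in% c("sse", "both")) {
    if (is.null(background)) background <- compute_background(target_sse,
                                                              alphabet)
    profile <- build_profile(query, hits, target_sse, alphabet, background,
                             subst = subst, tau = tau, hit_seqs = targets)
    sources$sse_pssm <- window_features(profile$pssm, window_size)
  }
  if (feature_set %in% c("aa", "both")) {
    aa_bg <- compute_background(targets, sse_alphabet("aa20"))
    aa_profile <- build_aa_profile(query, hits, targets, aa_bg, tau = 0)
    sources$aa_pssm <- window_features(aa_profile$pssm, window_size)
  }
  if (aa_type)
    sources$aa_type <- matrix(encode_amino_acid(unname(query[1])),
                              ncol = 1, dimnames = list(NULL, "type"))
  list(features = merge_features(sources), profile = profile,
       aa_profile = aa_profile, hits = hits)
}

#' Train and evaluate on a synthetic benchmark
#'
#' For every training query, builds the requested feature set against the
#' benchmark's shared target library, stacks residues, fits the
#' bootstrap-vote ensemble, then predicts every test query and scores the
#' predictions with the full metric suite.
#'
#' @param benchmark A [generate_benchmark()] result.
#' @param feature_set `"sse"`, `"aa"` or `"both"`.
#' @param window_size Odd window width.
#' @param tau Pseudocount mass for the SSE profile.
#' @param subst Substitution matrix for pseudocounts; when `NULL` and
#'   `tau > 0`, one is built from the benchmark's own target SSE strings
#'   (each string paired with itself jittered is not available, so pairs
#'   of library strings aligned by the search engine are used).
#' @param ensemble An [ensemble_params()]; its alphabet must match the
#'   benchmark's.
#' @param search [search_params()] used for profile construction.
#' @return List with `report` (an `evaluation_report`), `model`,
#'   `predicted` (named SSE strings), `actual`.
#' @export
run_benchmark <- function(benchmark, feature_set = "sse", window_size = 5L,
                          tau = 0, subst = NULL,
                          ensemble = ensemble_params(
                            alphabet = benchmark$alphabet),
                          search = search_params()) {
  alphabet <- benchmark$alphabet
  background <- compute_background(benchmark$target_sse, alphabet)
  featurize <- function(qrec) {
    query_features(stats::setNames(qrec$seq, qrec$id), benchmark$targets,
                   benchmark$target_sse, alphabet, background,
                   subst = subst, tau = tau, window_size = window_size,
                   feature_set = feature_set, params = search)$features
  }
  train_feats <- lapply(benchmark$train, featurize)
  labels <- unlist(lapply(benchmark$train,
                          function(q) strsplit(q$sse, "")[[1]]))
  x <- do.call(rbind, train_feats)
  model <- fit_sse_ensemble(x, labels, ensemble)
  predicted <- vapply(benchmark$test, function(qrec)
    predict_sse(model, featurize(qrec)), character(1))
  names(predicted) <- vapply(benchmark$test, `[[`, character(1), "id")
  actual <- stats::setNames(
    vapply(benchmark$test, `[[`, character(1), "sse"), names(predicted))
  report <- evaluate_predictions(actual, predicted, alphabet)
  list(report = report, model = model, predicted = predicted,
       actual = actual)
}
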