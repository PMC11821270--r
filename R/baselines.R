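#' Random-classifier similarity scores
#'
#' The random classifier draws each pair's similarity score independently
#' from Uniform(0, 1). Deterministic given `seed`.
#'
#' @param pairs data.frame with `id1`, `id2`.
#' @param seed integer seed.
#' @return data.frame `id1`, `id2`, `S`.
#' @export
random_classifier_scores <- function(pairs, seed) {
  out <- pairs[, c("id1", "id2"), drop = FALSE]
  out$S <- local_seed(seed, stats::runif(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Random-annotator label shuffle
#'
#' The random annotator permutes the sibling/unlabeled labels across all
#' pairs, preserving the label counts while destroying any association with
#' the pairs' scores.
#'
#' @param dataset an `fp_pair_dataset`.
#' @param seed integer seed.
#' @return An `fp_pair_dataset` with permuted labels (gate thresholds kept
#'   for provenance; the labels no longer reflect them).
#' @export
random_annotator_labels <- function(dataset, seed) {
  stopifnot(inherits(dataset, "fp_pair_dataset"))
  perm <- local_seed(seed, sample.int(nrow(dataset)))
  dataset$label <- dataset$label[perm]
  dataset
}

#' Resampled baseline report
#'
#' Evaluates one of the two empirical random baselines with the same balanced
#' resampling protocol and report schema as real methods.
#'
#' * `random_classifier`: per iteration, fresh Uniform(0,1) scores for all
#'   pairs of the balanced sample.
#' * `random_annotator`: the supplied method `scores` are kept fixed; per
#'   iteration the balanced sample's labels are shuffled.
#'
#' Per-iteration seeds are derived from the master seed plus the iteration
#' index, so any single iteration is reproducible in isolation.
#'
#' @param dataset an `fp_pair_dataset`.
#' @param kind `"random_classifier"` or `"random_annotator"`.
#' @param scores method scores (`id1`, `id2`, `S`), required for the random
#'   annotator.
#' @param n_iter number of iterations (default 100).
#' @param seed integer master seed.
#' @return An `fp_report`.
#' @export
baseline_report <- function(dataset,
                            kind = c("random_classifier", "random_annotator"),
                            scores = NULL, n_iter = 100, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "fp_pair_dataset"), n_iter >= 1)
  if (kind == "random_annotator" && is.null(scores)) {
    stop("the random annotator shuffles labels under a method's fixed scores;",
         " supply `scores`")
  }
  rows <- matrix(NA_real_, n_iter, length(report_metric_names),
                 dimnames = list(NULL, report_metric_names))
  for (i in seq_len(n_iter)) {
    bal <- undersample_balanced(dataset, seed = seed + i)
    if (kind == "random_classifier") {
      sc <- random_classifier_scores(bal, seed = seed + n_iter + i)
      ev <- evaluate_scores(sc, bal)
    } else {
      shuf <- random_annotator_labels(bal, seed = seed + n_iter + i)
      key <- paste(scores$id1, scores$id2) %in% paste(shuf$id1, shuf$id2)
      ev <- evaluate_scores(scores[key, , drop = FALSE], shuf)
    }
    rows[i, ] <- metrics(ev)[report_metric_names]
  }
  structure(list(method = kind, kernel = "baseline", n_iter = n_iter,
                 seed = seed, mean = colMeans(rows),
                 sd = if (n_iter > 1) apply(rows, 2L, stats::sd) else NULL,
                 iterations = as.data.frame(rows)),
            class = "fp_report")
}
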