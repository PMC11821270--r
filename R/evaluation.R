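#' Confusion counts at a similarity threshold
#'
#' A scored pair is predicted positive when `S >= tau_s` (inclusive). Sibling
#' pairs are the positives; unlabeled pairs are counted as negatives — the
#' positive-versus-unlabeled convention, so "FP" means "predicted sibling
#' among unlabeled pairs", some of which may be real siblings.
#'
#' @param scores data.frame `id1`, `id2`, `S` (e.g. from [pair_scores()]).
#' @param labels an `fp_pair_dataset` covering every scored pair.
#' @param tau_s similarity threshold.
#' @return list with integer `TP`, `FP`, `FN`, `TN` and the `tau_s` used.
#' @export
confusion_at <- function(scores, labels, tau_s) {
  sib <- match_pair_labels(scores, labels)
  pos <- scores$S >= tau_s
  list(TP = sum(pos & sib), FP = sum(pos & !sib),
       FN = sum(!pos & sib), TN = sum(!pos & !sib), tau_s = tau_s)
}

# sibling indicator for scored pairs, erroring on pairs without a label
match_pair_labels <- function(scores, labels) {
  key <- paste(scores$id1, scores$id2)
  lkey <- paste(labels$id1, labels$id2)
  idx <- match(key, lkey)
  if (anyNA(idx)) {
    stop("scored pair absent from labeled dataset: ", key[is.na(idx)][1L])
  }
  labels$label[idx] == "sibling"
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, F1 their harmonic mean.
#' When no pair is predicted positive, precision is undefined and reported as
#' 0 with `precision_defined = FALSE`; F1 is 0 when precision and recall are
#' both 0.
#'
#' @param counts list with `TP`, `FP`, `FN` (e.g. from [confusion_at()]).
#' @return list `precision`, `recall`, `f1`, `precision_defined`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  pdef <- (tp + fp) > 0
  prec <- if (pdef) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, precision_defined = pdef)
}

# Per-tau_s curve over the distinct observed scores, ascending.
# Returns tau (ascending), tp, pp (predicted positives), n_pos, n, and the
# derived precision/recall/f1 vectors.
threshold_curve <- function(S, sib) {
  n <- length(S)
  n_pos <- sum(sib)
  o <- order(S, decreasing = TRUE)
  s_sorted <- S[o]
  tp_cum <- cumsum(sib[o])
  # last index of each distinct score block (descending)
  last <- which(!duplicated(s_sorted, fromLast = TRUE))
  tau_desc <- s_sorted[last]
  tp <- tp_cum[last]
  pp <- last
  # ascending tau for smallest-tie argmax
  k <- rev(seq_along(tau_desc))
  tau <- tau_desc[k]; tp <- tp[k]; pp <- pp[k]
  prec <- ifelse(pp > 0, tp / pp, 0)
  rec <- if (n_pos > 0) tp / n_pos else rep(0, length(tp))
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(tau = tau, tp = tp, pp = pp, n_pos = n_pos, n = n,
       precision = prec, recall = rec, f1 = f1)
}

#' PR and ROC area under the curve for scored pairs
#'
#' Curves are built over all distinct similarity thresholds. ROC AUC uses the
#' tie-aware rank (Mann-Whitney) identity, equivalent to trapezoids through
#' tied blocks; PR AUC uses step-wise summation over descending thresholds
#' (no interpolation), i.e. average precision.
#'
#' @param scores data.frame `id1`, `id2`, `S`.
#' @param labels an `fp_pair_dataset`.
#' @return list `pr_auc`, `roc_auc`.
#' @export
pr_roc_auc <- function(scores, labels) {
  sib <- match_pair_labels(scores, labels)
  auc_from_scores(scores$S, sib)
}

auc_from_scores <- function(S, sib) {
  n_pos <- sum(sib); n_neg <- sum(!sib)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: need at least one sibling and one unlabeled pair")
  }
  r <- rank(S)  # mid-ranks for ties
  roc <- (sum(r[sib]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  cv <- threshold_curve(S, sib)
  # descending thresholds for the step sum
  tp <- rev(cv$tp); prec <- rev(cv$precision); rec <- rev(cv$recall)
  pr <- sum(diff(c(0, rec)) * prec)
  list(pr_auc = pr, roc_auc = roc)
}

#' Recall-weighted similarity-score separation
#'
#' The separation statistic is the difference between the mean similarity
#' score of scored sibling pairs and scored unlabeled pairs, weighted by the
#' coverage recall — the fraction of all dataset siblings that the method
#' scores (is annotatable for) at the current prediction threshold. The
#' weight penalizes methods that cannot annotate test-set siblings; the
#' result lies in \[-1, 1\] and is independent of the similarity threshold.
#'
#' @param scores data.frame `id1`, `id2`, `S`; must contain at least one
#'   sibling and one unlabeled pair.
#' @param labels an `fp_pair_dataset`.
#' @param coverage_recall weight in \[0,1\]; defaults to the fraction of
#'   `labels`' siblings present in `scores`.
#' @return The weighted separation (numeric scalar).
#' @export
delta_s <- function(scores, labels, coverage_recall = NULL) {
  sib <- match_pair_labels(scores, labels)
  if (!sum(sib) || !sum(!sib)) {
    stop("separation undefined: need scored pairs of both classes")
  }
  if (is.null(coverage_recall)) {
    n_sib_all <- sum(labels$label == "sibling")
    coverage_recall <- sum(sib) / n_sib_all
  }
  stopifnot(coverage_recall >= 0, coverage_recall <= 1)
  coverage_recall * (mean(scores$S[sib]) - mean(scores$S[!sib]))
}

# ---- the (tau_p, tau_s) sweep engine ---------------------------------------

#' Evaluate a method over the joint threshold sweep
#'
#' Runs the full assessment of one method against a labeled pair dataset:
#' for every prediction-score threshold tau_p on the grid (the sorted
#' distinct internal scores plus a `-Inf` sentinel), predictions are
#' thresholded into annotation sets, pairs where both proteins are annotated
#' are scored with the chosen kernel, and the per-threshold metrics are
#' accumulated. Reported are the maximum F1 over the joint grid (ties broken
#' toward smaller tau_p, then smaller tau_s), precision/recall at the
#' optimum, PR/ROC AUC at the optimal tau_p (sweeping tau_s only), the
#' recall-weighted separation at the optimal tau_p and its maximum over
#' tau_p, and the maximum recall under the predicted-positive budget
#' (strictly fewer than half of the scored pairs called positive).
#'
#' Thresholds that leave scored pairs of only one class (e.g. a tau_p so
#' strict that only sibling pairs remain annotatable) are skipped: with
#' unlabeled pairs as the negatives, a single-class subset makes precision
#' degenerate and the separation and AUC statistics undefined.
#'
#' Embedding kernels take no prediction threshold; their grid is the single
#' `-Inf` sentinel.
#'
#' @param predictions an `fp_predictions` (set kernels); `NULL` for embedding
#'   kernels.
#' @param dataset an `fp_pair_dataset`.
#' @param kernel,ia,dag,embeddings,ec_level,euclidean_variant passed to
#'   [pair_scores()].
#' @param tau_p_grid optional numeric grid overriding the default.
#' @param delta_s_recall `"coverage"` (default) weights the separation by the
#'   fraction of dataset siblings scored at tau_p; `"at_opt"` uses the recall
#'   at the optimal similarity threshold instead.
#' @return An object of class `fp_eval`; see [metrics()] for the flat metric
#'   vector and `$sweep` for the per-tau_p table.
#' @export
evaluate_method <- function(predictions = NULL, dataset,
                            kernel = "jaccard", ia = NULL, dag = NULL,
                            embeddings = NULL, ec_level = NULL,
                            euclidean_variant = "half_distance",
                            tau_p_grid = NULL,
                            delta_s_recall = c("coverage", "at_opt")) {
  delta_s_recall <- match.arg(delta_s_recall)
  stopifnot(inherits(dataset, "fp_pair_dataset"))
  embedding_kernel <- kernel %in% c("euclidean", "cosine")
  if (is.null(tau_p_grid)) {
    tau_p_grid <- if (embedding_kernel || is.null(predictions)) -Inf else
      c(-Inf, sort(unique(predictions$score)))
  }
  n_sib_all <- sum(dataset$label == "sibling")
  score_at <- function(tau_p) {
    if (embedding_kernel) {
      pair_scores(dataset, embeddings = embeddings, kernel = kernel,
                  euclidean_variant = euclidean_variant)
    } else {
      sets <- threshold_annotations(predictions, tau_p)
      pair_scores(dataset, sets = sets, kernel = kernel, ia = ia, dag = dag,
                  ec_level = ec_level)
    }
  }
  rows <- lapply(tau_p_grid, function(tau_p) {
    sc <- score_at(tau_p)
    if (!nrow(sc)) return(NULL)
    sib <- match_pair_labels(sc, dataset)
    # a threshold that leaves only one class scored cannot be assessed in the
    # positive-vs-unlabeled design (precision degenerates); skip it
    if (!sum(sib) || !sum(!sib)) return(NULL)
    cv <- threshold_curve(sc$S, sib)
    i_f1 <- which.max(cv$f1)
    cov <- sum(sib) / n_sib_all
    ds <- {
      w <- if (delta_s_recall == "coverage") cov else cv$recall[i_f1]
      w * (mean(sc$S[sib]) - mean(sc$S[!sib]))
    }
    feasible <- cv$pp / cv$n < 0.5
    rec50 <- if (any(feasible)) max(cv$recall[feasible]) else 0
    data.frame(tau_p = tau_p, n_scored = cv$n, n_sib_scored = cv$n_pos,
               coverage = cov,
               f1max = cv$f1[i_f1], tau_s = cv$tau[i_f1],
               precision = cv$precision[i_f1], recall = cv$recall[i_f1],
               delta_s = ds, recall_ppf50 = rec50)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    stop("no prediction threshold leaves annotatable pairs of both classes")
  }
  sweep <- do.call(rbind, rows)
  i_opt <- which.max(sweep$f1max)  # first max: smallest tau_p
  tau_p_opt <- sweep$tau_p[i_opt]
  sc_opt <- score_at(tau_p_opt)
  sib_opt <- match_pair_labels(sc_opt, dataset)
  aucs <- if (sum(sib_opt) && sum(!sib_opt)) {
    auc_from_scores(sc_opt$S, sib_opt)
  } else list(pr_auc = NA_real_, roc_auc = NA_real_)
  i_ds <- if (all(is.na(sweep$delta_s))) NA_integer_ else
    which.max(sweep$delta_s)
  ap <- annotatable_pairs(
    if (embedding_kernel) {
      stats::setNames(as.list(rownames(embeddings)), rownames(embeddings))
    } else {
      threshold_annotations(predictions, tau_p_opt)
    }, dataset)
  structure(list(
    method = if (!is.null(predictions)) attr(predictions, "method") else kernel,
    kernel = kernel,
    f1max = sweep$f1max[i_opt],
    tau_p_opt = tau_p_opt,
    tau_s_opt = sweep$tau_s[i_opt],
    precision = sweep$precision[i_opt],
    recall = sweep$recall[i_opt],
    pr_auc = aucs$pr_auc,
    roc_auc = aucs$roc_auc,
    delta_s = sweep$delta_s[i_opt],
    delta_s_max = if (is.na(i_ds)) NA_real_ else sweep$delta_s[i_ds],
    tau_p_delta_s_max = if (is.na(i_ds)) NA_real_ else sweep$tau_p[i_ds],
    recall_max_ppf50 = max(sweep$recall_ppf50),
    frac_pairs = attr(ap, "frac_pairs"),
    frac_siblings = attr(ap, "frac_siblings"),
    n_scored = sweep$n_scored[i_opt],
    n_sib_scored = sweep$n_sib_scored[i_opt],
    sweep = sweep
  ), class = "fp_eval")
}

#' Evaluate precomputed pairwise similarity scores
#'
#' The single-threshold counterpart of [evaluate_method()], for methods (or
#' baselines) that provide pairwise similarity scores directly rather than
#' per-protein predictions.
#'
#' @param scores data.frame `id1`, `id2`, `S`.
#' @param dataset an `fp_pair_dataset` covering the scored pairs.
#' @param coverage_recall weight for the separation statistic; defaults to
#'   the scored fraction of dataset siblings.
#' @return An `fp_eval`.
#' @export
evaluate_scores <- function(scores, dataset, coverage_recall = NULL) {
  stopifnot(inherits(dataset, "fp_pair_dataset"))
  sib <- match_pair_labels(scores, dataset)
  if (!nrow(scores)) stop("no scored pairs")
  cv <- threshold_curve(scores$S, sib)
  i_f1 <- which.max(cv$f1)
  n_sib_all <- sum(dataset$label == "sibling")
  cov <- coverage_recall %||% (sum(sib) / n_sib_all)
  ds <- if (sum(sib) && sum(!sib)) {
    cov * (mean(scores$S[sib]) - mean(scores$S[!sib]))
  } else NA_real_
  aucs <- if (sum(sib) && sum(!sib)) auc_from_scores(scores$S, sib) else
    list(pr_auc = NA_real_, roc_auc = NA_real_)
  feasible <- cv$pp / cv$n < 0.5
  structure(list(
    method = "scores", kernel = "precomputed",
    f1max = cv$f1[i_f1], tau_p_opt = -Inf, tau_s_opt = cv$tau[i_f1],
    precision = cv$precision[i_f1], recall = cv$recall[i_f1],
    pr_auc = aucs$pr_auc, roc_auc = aucs$roc_auc,
    delta_s = ds, delta_s_max = ds, tau_p_delta_s_max = -Inf,
    recall_max_ppf50 = if (any(feasible)) max(cv$recall[feasible]) else 0,
    frac_pairs = nrow(scores) / nrow(dataset),
    frac_siblings = sum(sib) / n_sib_all,
    n_scored = cv$n, n_sib_scored = cv$n_pos,
    sweep = NULL
  ), class = "fp_eval")
}

#' @export
print.fp_eval <- function(x, digits = 3, ...) {
  cat("Method evaluation (", x$method, ", kernel ", x$kernel, ")\n", sep = "")
  cat(sprintf("  F1max %.*f at tau_p=%s, tau_s=%.*g (P %.*f, R %.*f)\n",
              digits, x$f1max, format(x$tau_p_opt), digits, x$tau_s_opt,
              digits, x$precision, digits, x$recall))
  cat(sprintf("  deltaS %.*f (max %.*f), RecallmaxPPf50 %.*f\n",
              digits, x$delta_s, digits, x$delta_s_max, digits,
              x$recall_max_ppf50))
  cat(sprintf("  PR AUC %.*f, ROC AUC %.*f | %d scored pairs (%d siblings)\n",
              digits, x$pr_auc, digits, x$roc_auc, x$n_scored,
              x$n_sib_scored))
  invisible(x)
}

#' Flat metric vector of an evaluation
#'
#' @param x an `fp_eval`.
#' @return Named numeric vector of the headline metrics.
#' @export
metrics <- function(x) {
  stopifnot(inherits(x, "fp_eval"))
  c(f1max = x$f1max, tau_p_opt = x$tau_p_opt, tau_s_opt = x$tau_s_opt,
    precision = x$precision, recall = x$recall,
    pr_auc = x$pr_auc, roc_auc = x$roc_auc,
    delta_s = x$delta_s, delta_s_max = x$delta_s_max,
    recall_max_ppf50 = x$recall_max_ppf50,
    frac_pairs = x$frac_pairs, frac_siblings = x$frac_siblings)
}

# ---- spec-facing convenience wrappers --------------------------------------

#' Maximum F1 over the joint threshold grid
#'
#' @inheritParams evaluate_method
#' @param ... further arguments to [evaluate_method()].
#' @return list `f1max`, `tau_p_opt`, `tau_s_opt`.
#' @export
sweep_f1max <- function(predictions, dataset, kernel = "jaccard", ...) {
  ev <- evaluate_method(predictions, dataset, kernel = kernel, ...)
  list(f1max = ev$f1max, tau_p_opt = ev$tau_p_opt, tau_s_opt = ev$tau_s_opt)
}

#' Maximum separation over the prediction-threshold grid
#'
#' @inheritParams sweep_f1max
#' @return list `delta_s_max`, `tau_p`.
#' @export
delta_s_max <- function(predictions, dataset, kernel = "jaccard", ...) {
  ev <- evaluate_method(predictions, dataset, kernel = kernel, ...)
  list(delta_s_max = ev$delta_s_max, tau_p = ev$tau_p_delta_s_max)
}

#' Maximum recall under the predicted-positive budget
#'
#' Maximum recall over both thresholds subject to strictly fewer than half of
#' the scored pairs being called positive; 0 when no threshold pair satisfies
#' the budget.
#'
#' @inheritParams sweep_f1max
#' @return Numeric scalar.
#' @export
recall_max_ppf50 <- function(predictions, dataset, kernel = "jaccard", ...) {
  evaluate_method(predictions, dataset, kernel = kernel, ...)$recall_max_ppf50
}

# ---- resampled evaluation ---------------------------------------------------

report_metric_names <- c("f1max", "tau_p_opt", "tau_s_opt", "precision",
                         "recall", "pr_auc", "roc_auc", "delta_s",
                         "delta_s_max", "recall_max_ppf50", "frac_pairs",
                         "frac_siblings")

#' Resampled (balanced under-sampling) evaluation of a method
#'
#' Repeats balanced under-sampling of the unlabeled pairs `n_iter` times
#' (each iteration's sample seed derived as `seed + iteration`), evaluates
#' the method on each balanced dataset with [evaluate_method()] (or
#' [evaluate_scores()] when `scores` is given), and aggregates the mean and
#' standard deviation of every metric. Fully reproducible from `seed`.
#'
#' @inheritParams evaluate_method
#' @param scores optional precomputed data.frame `id1`, `id2`, `S`; used
#'   instead of `predictions` when given.
#' @param n_iter number of under-sampling iterations (default 100).
#' @param seed integer master seed.
#' @param ... further arguments to [evaluate_method()].
#' @return An object of class `fp_report` with elements `method`, `kernel`,
#'   `n_iter`, `seed`, `mean`, `sd` (named vectors) and `iterations` (one row
#'   per iteration).
#' @export
run_resampled_evaluation <- function(predictions = NULL, dataset,
                                     kernel = "jaccard", scores = NULL,
                                     n_iter = 100, seed = 1, ...) {
  stopifnot(inherits(dataset, "fp_pair_dataset"), n_iter >= 1)
  rows <- matrix(NA_real_, nrow = n_iter, ncol = length(report_metric_names),
                 dimnames = list(NULL, report_metric_names))
  for (i in seq_len(n_iter)) {
    bal <- undersample_balanced(dataset, seed = seed + i)
    ev <- if (!is.null(scores)) {
      key <- paste(scores$id1, scores$id2) %in% paste(bal$id1, bal$id2)
      evaluate_scores(scores[key, , drop = FALSE], bal)
    } else {
      evaluate_method(predictions, bal, kernel = kernel, ...)
    }
    rows[i, ] <- metrics(ev)[report_metric_names]
  }
  method <- if (!is.null(scores)) "scores" else
    attr(predictions, "method") %||% kernel
  structure(list(method = method, kernel = kernel, n_iter = n_iter,
                 seed = seed,
                 mean = colMeans(rows),
                 sd = if (n_iter > 1) apply(rows, 2L, stats::sd) else NULL,
                 iterations = as.data.frame(rows)),
            class = "fp_report")
}

#' @export
print.fp_report <- function(x, digits = 3, ...) {
  cat("Resampled evaluation:", x$method, "| kernel", x$kernel,
      "|", x$n_iter, "iterations (seed", paste0(x$seed, ")\n"))
  cat("NOTE: unlabeled pairs are counted as negatives",
      "(positive-vs-unlabeled design).\n")
  m <- x$mean
  s <- x$sd %||% rep(NA_real_, length(m))
  for (k in c("f1max", "delta_s", "delta_s_max", "recall_max_ppf50",
              "pr_auc", "roc_auc", "precision", "recall")) {
    cat(sprintf("  %-18s %.*f +/- %.*f\n", k, digits, m[[k]], digits, s[[k]]))
  }
  invisible(x)
}

#' @export
summary.fp_report <- function(object, ...) {
  data.frame(metric = names(object$mean), mean = unname(object$mean),
             sd = if (is.null(object$sd)) NA_real_ else unname(object$sd))
}

#' Evaluate binary reference annotations against the sibling gate
#'
#' For an annotation source with binary same/different labels (e.g. matched
#' third-level EC numbers, the "ideal predictor" protocol), every `same`
#' pair is predicted positive — no threshold sweep — and precision/recall are
#' aggregated over balanced resamples.
#'
#' @param pair_labels data.frame `id1`, `id2`, `same` (logical), covering the
#'   dataset pairs; uncovered pairs are dropped with a warning.
#' @param dataset an `fp_pair_dataset`.
#' @param n_iter,seed as in [run_resampled_evaluation()].
#' @return list `precision`, `recall` (means), `sd` (named vector),
#'   `iterations` data.frame.
#' @export
evaluate_binary_reference <- function(pair_labels, dataset, n_iter = 100,
                                      seed = 1) {
  key <- paste(pair_labels$id1, pair_labels$id2)
  dkey <- paste(dataset$id1, dataset$id2)
  if (!all(dkey %in% key)) {
    warning(sum(!dkey %in% key), " dataset pair(s) without reference label ",
            "dropped")
  }
  rows <- matrix(NA_real_, n_iter, 2L,
                 dimnames = list(NULL, c("precision", "recall")))
  for (i in seq_len(n_iter)) {
    bal <- undersample_balanced(dataset, seed = seed + i)
    bkey <- paste(bal$id1, bal$id2)
    idx <- match(bkey, key)
    keep <- !is.na(idx)
    same <- pair_labels$same[idx[keep]]
    sib <- bal$label[keep] == "sibling"
    cf <- list(TP = sum(same & sib), FP = sum(same & !sib),
               FN = sum(!same & sib))
    prf <- precision_recall_f1(cf)
    rows[i, ] <- c(prf$precision, prf$recall)
  }
  list(precision = mean(rows[, "precision"]), recall = mean(rows[, "recall"]),
       sd = apply(rows, 2L, stats::sd), iterations = as.data.frame(rows))
}

#' Pairwise significance tests between method reports
#'
#' Compares methods' per-iteration metric samples with the two-sided Wilcoxon
#' rank-sum test and Student's t-test, adjusting p-values within each metric
#' family by Benjamini-Hochberg.
#'
#' @param reports named list of `fp_report` objects sharing `n_iter`.
#' @param which_metrics metrics to compare (default the separation, F1max and
#'   the two AUCs).
#' @return data.frame with one row per method pair and metric: raw and
#'   BH-adjusted p-values for both tests.
#' @export
compare_methods <- function(reports,
                            which_metrics = c("delta_s", "f1max", "pr_auc",
                                              "roc_auc")) {
  stopifnot(length(reports) >= 2L)
  n_iters <- vapply(reports, function(r) as.numeric(r$n_iter), 1)
  if (length(unique(n_iters)) != 1L) {
    stop("reports have mismatched iteration counts")
  }
  nm <- names(reports) %||% vapply(reports, function(r) r$method, "")
  combos <- utils::combn(seq_along(reports), 2L)
  out <- list()
  for (metric in which_metrics) {
    rows <- apply(combos, 2L, function(ij) {
      a <- reports[[ij[1L]]]$iterations[[metric]]
      b <- reports[[ij[2L]]]$iterations[[metric]]
      w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
      tt <- if (stats::sd(c(a, b)) == 0) list(p.value = 1) else
        suppressWarnings(stats::t.test(a, b))
      data.frame(metric = metric, method1 = nm[ij[1L]], method2 = nm[ij[2L]],
                 p_wilcoxon = if (is.na(w$p.value)) 1 else w$p.value,
                 p_ttest = if (is.na(tt$p.value)) 1 else tt$p.value)
    })
    block <- do.call(rbind, rows)
    block$p_wilcoxon_bh <- stats::p.adjust(block$p_wilcoxon, method = "BH")
    block$p_ttest_bh <- stats::p.adjust(block$p_ttest, method = "BH")
    out[[metric]] <- block
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
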