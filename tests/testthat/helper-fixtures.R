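# Shared fixtures and independent brute-force oracles.
# The oracles are deliberately naive (explicit loops, direct counting) and
# share no code with the package internals they check.

diamond_dag <- function() {
  ontology(c("R", "A", "B", "C", "D"),
           list(A = "R", B = "A", C = "A", D = c("B", "C")))
}

# a labeled pair dataset with forced gate outcomes; each pair uses its own
# protein ids unless `ids` are supplied
make_dataset <- function(n_sib, n_unl, scores_sib = NULL, scores_unl = NULL) {
  n <- n_sib + n_unl
  pairs <- data.frame(
    id1 = sprintf("a%03d", seq_len(n)),
    id2 = sprintf("b%03d", seq_len(n)),
    tm = c(rep(0.9, n_sib), rep(0.2, n_unl)),
    snn = c(rep(0.99, n_sib), rep(0.2, n_unl)),
    identity = runif(n, 0, 89),
    stringsAsFactors = FALSE)
  ds <- label_siblings(pairs)
  if (!is.null(scores_sib)) {
    attr(ds, "scores") <- data.frame(
      id1 = ds$id1, id2 = ds$id2, S = c(scores_sib, scores_unl))
  }
  ds
}

dataset_scores <- function(ds) attr(ds, "scores")

# random small prediction + pair instance for oracle-equivalence checks
random_instance <- function(seed, n_prot = 6, n_terms = 5) {
  set.seed(seed)
  prots <- sprintf("p%d", seq_len(n_prot))
  terms <- letters[seq_len(n_terms)]
  rows <- expand.grid(protein = prots, term = terms,
                      stringsAsFactors = FALSE)
  rows <- rows[runif(nrow(rows)) < 0.5, ]
  rows$score <- round(runif(nrow(rows)), 2)
  ij <- combn(n_prot, 2)
  pairs <- data.frame(id1 = prots[ij[1, ]], id2 = prots[ij[2, ]],
                      stringsAsFactors = FALSE)
  pairs$tm <- ifelse(runif(nrow(pairs)) < 0.4, 0.9, 0.3)
  pairs$snn <- ifelse(pairs$tm > 0.5, 0.99, 0.3)
  pairs$identity <- runif(nrow(pairs), 0, 89)
  list(pred = prediction_table(rows$protein, rows$term, rows$score),
       dataset = label_siblings(pairs))
}

naive_sim <- function(a, b, kernel) {
  i <- length(intersect(a, b))
  if (kernel == "binary_shared") return(as.numeric(i > 0))
  i / length(union(a, b))
}

# exhaustive enumeration over every (tau_p, tau_s) candidate
oracle_eval <- function(pred, dataset, kernel = "jaccard") {
  taus_p <- c(-Inf, sort(unique(pred$score)))
  n_sib_all <- sum(dataset$label == "sibling")
  best <- list(f1 = -1, tau_p = NA, tau_s = NA)
  dsmax <- -Inf
  rec50 <- 0
  for (tp in taus_p) {
    keep <- pred[pred$score >= tp, , drop = FALSE]
    sets <- split(keep$term, keep$protein)
    rows <- dataset[dataset$id1 %in% names(sets) &
                      dataset$id2 %in% names(sets), , drop = FALSE]
    if (!nrow(rows)) next
    S <- mapply(function(a, b) naive_sim(sets[[a]], sets[[b]], kernel),
                rows$id1, rows$id2, USE.NAMES = FALSE)
    sib <- rows$label == "sibling"
    if (!sum(sib) || !sum(!sib)) next
    dsmax <- max(dsmax,
                 (sum(sib) / n_sib_all) * (mean(S[sib]) - mean(S[!sib])))
    for (ts in sort(unique(S))) {
      pos <- S >= ts
      TP <- sum(pos & sib); FP <- sum(pos & !sib); FN <- sum(!pos & sib)
      prec <- if (TP + FP > 0) TP / (TP + FP) else 0
      rec <- if (TP + FN > 0) TP / (TP + FN) else 0
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      if (f1 > best$f1 + 1e-12) best <- list(f1 = f1, tau_p = tp, tau_s = ts)
      if (sum(pos) / length(S) < 0.5) rec50 <- max(rec50, rec)
    }
  }
  list(f1max = best$f1, tau_p = best$tau_p, tau_s = best$tau_s,
       delta_s_max = dsmax, recall_ppf50 = rec50)
}

# trapezoid ROC over all distinct thresholds (tie blocks traversed diagonally)
oracle_roc_auc <- function(S, pos) {
  ths <- c(Inf, sort(unique(S), decreasing = TRUE))
  tpr <- vapply(ths, function(t) sum(S >= t & pos), 1) / sum(pos)
  fpr <- vapply(ths, function(t) sum(S >= t & !pos), 1) / sum(!pos)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# step-wise PR summation over descending distinct thresholds
oracle_pr_auc <- function(S, pos) {
  ths <- sort(unique(S), decreasing = TRUE)
  tp <- vapply(ths, function(t) sum(S >= t & pos), 1)
  pp <- vapply(ths, function(t) sum(S >= t), 1)
  sum(diff(c(0, tp / sum(pos))) * (tp / pp))
}
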