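test_that("confusion counting and P/R/F1 follow the conventions", {
  ds <- make_dataset(2, 2)
  sc <- data.frame(id1 = ds$id1, id2 = ds$id2, S = c(1, 0.2, 0.9, 0.1))
  cf <- confusion_at(sc, ds, 0.5)
  expect_equal(cf[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  cf0 <- confusion_at(sc, ds, 0)
  expect_equal(cf0$TP + cf0$FP, 4L)      # tau_s = 0 calls everything positive
  expect_error(
    confusion_at(data.frame(id1 = "x", id2 = "y", S = 1), ds, 0.5),
    "absent")

  prf <- precision_recall_f1(list(TP = 1693, FP = 1927 - 1693,
                                  FN = 70735 - 1693))
  expect_equal(round(prf$precision, 4), 0.8786)
  expect_equal(round(prf$recall, 4), 0.0239)
  expect_equal(precision_recall_f1(list(TP = 5, FP = 0, FN = 0))$f1, 1)
  expect_equal(precision_recall_f1(list(TP = 1, FP = 1, FN = 0))$f1, 2 / 3)
  none <- precision_recall_f1(list(TP = 0, FP = 0, FN = 3))
  expect_equal(none$precision, 0)
  expect_false(none$precision_defined)
  expect_equal(none$f1, 0)
})

test_that("joint sweep equals exhaustive enumeration on small instances", {
  for (seed in c(1, 2, 3, 4, 5)) {
    inst <- random_instance(seed)
    if (sum(inst$dataset$label == "sibling") == 0) next
    orc <- oracle_eval(inst$pred, inst$dataset)
    got <- evaluate_method(inst$pred, inst$dataset, kernel = "jaccard")
    expect_equal(got$f1max, orc$f1max, tolerance = 1e-12)
    expect_equal(got$tau_p_opt, orc$tau_p)
    expect_equal(got$tau_s_opt, orc$tau_s)
    expect_equal(got$delta_s_max, orc$delta_s_max, tolerance = 1e-12)
    expect_equal(got$recall_max_ppf50, orc$recall_ppf50, tolerance = 1e-12)
    # F1max dominates F1 at every individual threshold pair by construction
    sw <- sweep_f1max(inst$pred, inst$dataset)
    expect_identical(sw$f1max, got$f1max)
  }
})

test_that("degenerate sweeps behave: perfect separation and constant scores", {
  ds <- make_dataset(3, 5)
  perfect <- data.frame(id1 = ds$id1, id2 = ds$id2,
                        S = ifelse(ds$label == "sibling", 1, 0))
  ev <- evaluate_scores(perfect, ds)
  expect_equal(ev$f1max, 1)
  expect_equal(ev$roc_auc, 1)
  expect_equal(ev$pr_auc, 1)

  const <- data.frame(id1 = ds$id1, id2 = ds$id2, S = rep(0.4, 8))
  evc <- evaluate_scores(const, ds)
  # only one effective tau_s: the all-positive call, P = 3/8, R = 1
  expect_equal(evc$f1max, 2 * (3 / 8) / (3 / 8 + 1))
  expect_equal(evc$recall_max_ppf50, 0)  # PPf is 1; budget infeasible
  expect_equal(evc$roc_auc, 0.5)         # tie convention
})

test_that("AUCs agree with trapezoid/step oracles and pROC on random scores", {
  set.seed(19)
  for (i in 1:5) {
    n <- 30
    ds <- make_dataset(10, 20)
    S <- round(runif(n), 1)              # coarse grid forces ties
    sc <- data.frame(id1 = ds$id1, id2 = ds$id2, S = S)
    pos <- ds$label == "sibling"
    got <- pr_roc_auc(sc, ds)
    expect_equal(got$roc_auc, oracle_roc_auc(S, pos), tolerance = 1e-12)
    expect_equal(got$pr_auc, oracle_pr_auc(S, pos), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- as.numeric(pROC::auc(pROC::roc(pos, S, quiet = TRUE,
                                            direction = "<")))
      expect_equal(got$roc_auc, ref, tolerance = 1e-12)
    }
  }
  # single-class scored input is an error
  expect_error(pr_roc_auc(
    data.frame(id1 = "a001", id2 = "b001", S = 1), make_dataset(1, 1)),
    "undefined")
})

test_that("the separation statistic is coverage-weighted and bounded", {
  ds <- make_dataset(4, 4)
  sep <- data.frame(id1 = ds$id1, id2 = ds$id2,
                    S = ifelse(ds$label == "sibling", 1, 0))
  expect_equal(delta_s(sep, ds), 1)
  expect_equal(delta_s(sep, ds, coverage_recall = 0.5), 0.5)
  same <- data.frame(id1 = ds$id1, id2 = ds$id2, S = 0.3)
  expect_equal(delta_s(same, ds), 0)
  # partial coverage: scoring half the siblings halves the default weight
  part <- sep[c(1, 2, 5:8), ]
  expect_equal(delta_s(part, ds), 0.5)
  expect_error(delta_s(sep[ds$label == "sibling", ], ds), "both classes")
  set.seed(23)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    nsib <- sample(1:(n - 1), 1)
    d <- make_dataset(nsib, n - nsib)
    sc <- data.frame(id1 = d$id1, id2 = d$id2, S = runif(n))
    v <- delta_s(sc, d, coverage_recall = runif(1))
    expect_gte(v, -1); expect_lte(v, 1)
  }
})

test_that("delta_s_max maximizes over the prediction grid", {
  inst <- random_instance(7)
  got <- delta_s_max(inst$pred, inst$dataset)
  orc <- oracle_eval(inst$pred, inst$dataset)
  expect_equal(got$delta_s_max, orc$delta_s_max, tolerance = 1e-12)
  # single grid point: equals delta_s at that tau_p
  ds <- make_dataset(2, 3)
  pred <- prediction_table(c(ds$id1, ds$id2),
                           rep(c("t1", "t2", "t3", "t1", "t2"), 2),
                           rep(1, 10))
  one <- evaluate_method(pred, ds, tau_p_grid = 1)
  expect_equal(one$delta_s_max, one$delta_s)
})

test_that("budgeted recall matches its worked examples", {
  ds4 <- make_dataset(2, 2)
  sc4 <- data.frame(id1 = ds4$id1, id2 = ds4$id2, S = c(0.9, 0.8, 0.7, 0.1))
  expect_equal(evaluate_scores(sc4, ds4)$recall_max_ppf50, 0.5)
  ds10 <- make_dataset(2, 8)
  sc10 <- data.frame(id1 = ds10$id1, id2 = ds10$id2,
                     S = c(0.9, 0.8, 0.75, 0.7, 0.3, 0.25, 0.2, 0.15,
                           0.1, 0.05))
  expect_equal(evaluate_scores(sc10, ds10)$recall_max_ppf50, 1)
  # never exceeds the best recall achievable under half the calls
  set.seed(31)
  for (i in 1:20) {
    d <- make_dataset(3, 9)
    sc <- data.frame(id1 = d$id1, id2 = d$id2, S = runif(12))
    ev <- evaluate_scores(sc, d)
    expect_gte(ev$recall_max_ppf50, 0)
    expect_lte(ev$recall_max_ppf50, 1)
    # 12 pairs: budget allows at most 5 positives, so recall caps there
    expect_lte(ev$recall_max_ppf50, 5 / 3)
  }
})

test_that("metrics are invariant to pair-order permutation", {
  set.seed(41)
  ds <- make_dataset(5, 15)
  sc <- data.frame(id1 = ds$id1, id2 = ds$id2, S = runif(20))
  ev1 <- evaluate_scores(sc, ds)
  perm <- sample(20)
  ev2 <- evaluate_scores(sc[perm, ], ds)
  for (k in c("f1max", "tau_s_opt", "precision", "recall", "pr_auc",
              "roc_auc", "delta_s", "recall_max_ppf50")) {
    expect_equal(ev1[[k]], ev2[[k]], tolerance = 1e-12)
  }
})

test_that("resampled evaluation is deterministic and aggregates correctly", {
  w <- generate_world(n_proteins = 40, n_clusters = 4, seed = 2,
                      tm_sib = c(0.9, 0.02), tm_other = c(0.4, 0.05),
                      snn_sib = c(0.995, 0.002), snn_other = c(0.5, 0.05))
  ds <- label_siblings(w$pairs[c("id1", "id2", "tm", "snn", "identity")])
  pred <- simulate_predictor(w, seed = 4)
  rep1 <- run_resampled_evaluation(pred, ds, n_iter = 5, seed = 11)
  rep2 <- run_resampled_evaluation(pred, ds, n_iter = 5, seed = 11)
  expect_identical(rep1$iterations, rep2$iterations)
  expect_equal(nrow(rep1$iterations), 5)
  expect_equal(rep1$mean[["f1max"]], mean(rep1$iterations$f1max))
  # perfect predictor on a fully separated world: F1max 1 with zero spread
  expect_equal(unname(rep1$mean[["f1max"]]), 1)
  expect_equal(unname(rep1$sd[["f1max"]]), 0)
})

test_that("binary reference evaluation matches hand-computed rates", {
  ds <- make_dataset(3, 10)
  # reference identical to the gate labels
  ref <- data.frame(id1 = ds$id1, id2 = ds$id2, same = ds$label == "sibling")
  out <- evaluate_binary_reference(ref, ds, n_iter = 10, seed = 2)
  expect_equal(out$precision, 1)
  expect_equal(out$recall, 1)
  # all-"same" reference: recall 1, precision = balanced sibling fraction
  all_same <- transform(ref, same = TRUE)
  out2 <- evaluate_binary_reference(all_same, ds, n_iter = 10, seed = 2)
  expect_equal(out2$recall, 1)
  expect_equal(out2$precision, 0.5)
  # planted confusion: one sibling mislabeled, one unlabeled pair marked same
  ref3 <- ref
  ref3$same[1] <- FALSE           # a sibling the reference misses
  ref3$same[4] <- TRUE            # an unlabeled pair the reference calls same
  out3 <- evaluate_binary_reference(ref3, ds, n_iter = 50, seed = 3)
  expect_equal(out3$recall, 2 / 3, tolerance = 1e-9)
  # precision = 2/(2 + FP); FP = 1 only when pair 4 is in the balanced draw
  expect_lt(out3$precision, 1)
  expect_gt(out3$precision, 2 / 3 - 1e-9)
})

test_that("method comparison tests and BH adjustment behave", {
  ds <- make_dataset(4, 40)
  mk_rep <- function(shift, seed) {
    sc <- local({
      set.seed(seed)
      data.frame(id1 = ds$id1, id2 = ds$id2,
                 S = pmin(1, pmax(0, runif(44) +
                                    shift * (ds$label == "sibling"))))
    })
    run_resampled_evaluation(scores = sc, dataset = ds, n_iter = 20,
                             seed = seed)
  }
  good <- mk_rep(0.9, 1)
  bad <- mk_rep(0, 2)
  cmp <- compare_methods(list(good = good, bad = bad))
  row <- cmp[cmp$metric == "delta_s", ]
  expect_lt(row$p_wilcoxon, 1e-4)     # disjoint-support samples
  expect_true(all(cmp$p_wilcoxon_bh >= cmp$p_wilcoxon))
  # identical samples: both tests report no difference
  same <- compare_methods(list(a = good, b = good))
  expect_true(all(same$p_ttest > 0.99))
  expect_true(all(same$p_wilcoxon > 0.9))
  expect_error(compare_methods(list(
    a = good, b = run_resampled_evaluation(scores = dataset_scores(
      make_dataset(2, 10, 1:2 / 2, rep(0, 10))), dataset = make_dataset(2, 10),
      n_iter = 3, seed = 1))), "mismatched")
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.5), 0.5)
})
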