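test_that("world generation is reproducible and internally consistent", {
  w1 <- generate_world(n_proteins = 40, n_clusters = 4, seed = 5)
  w2 <- generate_world(n_proteins = 40, n_clusters = 4, seed = 5)
  expect_identical(w1$pairs, w2$pairs)
  expect_identical(w1$annotations, w2$annotations)
  expect_false(identical(
    generate_world(n_proteins = 40, n_clusters = 4, seed = 6)$pairs$tm,
    w1$pairs$tm))
  expect_equal(nrow(w1$pairs), choose(40, 2))
  expect_equal(length(unique(w1$proteins$cluster)), 4)
  # every protein in exactly one cluster; annotations follow the cluster
  expect_true(all(table(w1$proteins$cluster) == 10))
  a <- w1$annotations[["P0001"]]
  expect_true(all(startsWith(a, "T:1.")))
  # propagation-consistent truth: sets are closed under ancestors
  for (p in sample(names(w1$annotations), 5)) {
    s <- w1$annotations[[p]]
    expect_setequal(propagate(w1$ontology, s), s)
  }
  # same-cluster scores stochastically dominate cross-cluster scores
  expect_gt(mean(w1$pairs$tm[w1$pairs$same_cluster]),
            mean(w1$pairs$tm[!w1$pairs$same_cluster]))
  expect_gt(mean(w1$pairs$snn[w1$pairs$same_cluster]),
            mean(w1$pairs$snn[!w1$pairs$same_cluster]))
  expect_error(generate_world(n_proteins = 3, n_clusters = 2), "n_proteins")
})

test_that("default world metadata passes the orphan filters", {
  w <- generate_world(n_proteins = 30, n_clusters = 3, seed = 8)
  expect_equal(nrow(filter_orphans(w$proteins)), 30)
})

test_that("simulated predictor fidelity dials behave as documented", {
  w <- generate_world(n_proteins = 30, n_clusters = 3, seed = 9)
  clean <- simulate_predictor(w, seed = 1)
  expect_identical(simulate_predictor(w, seed = 1), clean)
  # perfect fidelity reproduces the truth exactly
  sets <- threshold_annotations(clean, -Inf)
  expect_setequal(names(sets), names(w$annotations))
  for (p in sample(names(sets), 5)) {
    expect_setequal(sets[[p]], w$annotations[[p]])
  }
  # coverage removes whole proteins
  half <- simulate_predictor(w, coverage = 0.5, seed = 2)
  expect_lt(length(unique(half$protein)), 30)
  # dropout 1 removes everything
  expect_error(simulate_predictor(w, dropout = 1, seed = 3), "no protein")
  # spurious terms come from outside the truth
  noisy <- simulate_predictor(w, spurious = 0.5, seed = 4)
  p1 <- noisy[noisy$protein == "P0001", ]
  expect_gt(length(setdiff(p1$term, w$annotations[["P0001"]])), 0)
  # EC source predicts the planted EC numbers
  ecp <- simulate_predictor(w, source = "ec", seed = 5)
  expect_equal(attr(ecp, "vocabulary"), "EC")
  expect_equal(ecp$term[ecp$protein == "P0001"], w$ec[["P0001"]])
})

test_that("simulated embeddings carry the planted cluster geometry", {
  w <- generate_world(n_proteins = 30, n_clusters = 3, seed = 10)
  emb <- simulate_embeddings(w, dim = 8, within_sd = 1e-6, between_sd = 2,
                             seed = 1)
  expect_identical(simulate_embeddings(w, dim = 8, within_sd = 1e-6,
                                       between_sd = 2, seed = 1), emb)
  same <- w$pairs[w$pairs$same_cluster, ][1:5, ]
  for (i in 1:5) {
    expect_equal(cosine_similarity(emb[same$id1[i], ], emb[same$id2[i], ]),
                 1, tolerance = 1e-6)
  }
  # separated clusters: embedding kernel beats chance
  emb2 <- simulate_embeddings(w, dim = 8, within_sd = 0.3, between_sd = 3,
                              seed = 2)
  # relabel with the planted truth as the gate outcome
  ds <- label_siblings(
    transform(w$pairs[c("id1", "id2", "tm", "snn", "identity")],
              tm = ifelse(w$pairs$same_cluster, 1, 0),
              snn = ifelse(w$pairs$same_cluster, 1, 0)))
  sc <- pair_scores(ds, embeddings = emb2, kernel = "cosine")
  expect_gt(pr_roc_auc(sc, ds)$roc_auc, 0.8)
})

test_that("fully separated score modes let the gate recover planted clusters", {
  w <- generate_world(n_proteins = 40, n_clusters = 4, seed = 11,
                      tm_sib = c(0.9, 0.02), tm_other = c(0.4, 0.05),
                      snn_sib = c(0.995, 0.002), snn_other = c(0.5, 0.05))
  ds <- label_siblings(w$pairs[c("id1", "id2", "tm", "snn", "identity")])
  expect_identical(ds$label == "sibling", w$pairs$same_cluster)
})

test_that("gate sensitivity against planted truth matches direct counting", {
  w <- generate_world(seed = 12)   # default, overlapping regime
  ds <- label_siblings(w$pairs[c("id1", "id2", "tm", "snn", "identity")])
  sib <- ds$label == "sibling"
  truth <- w$pairs$same_cluster
  # generator bookkeeping is the oracle: gate precision/recall computable
  gate_recall <- sum(sib & truth) / sum(truth)
  gate_prec <- sum(sib & truth) / sum(sib)
  expect_equal(sum(sib) / nrow(ds),
               mean(truth) * gate_recall / gate_prec, tolerance = 1e-9)
  expect_gt(gate_prec, 0.9)   # high-precision, low-recall regime
  expect_lt(gate_recall, 1)
})
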