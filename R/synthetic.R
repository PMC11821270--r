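#' Toy ontology of per-branch term chains
#'
#' One root with `n_branches` chains of `depth` terms hanging off it
#' (term at depth 1 is a child of the root, depth 2 a child of depth 1, ...).
#' Distinct branches share no non-root ancestor, so annotation sets drawn
#' from different branches are disjoint after propagation.
#'
#' @param n_branches number of chains.
#' @param depth terms per chain.
#' @return An `fp_ontology`; branch `b`'s terms are `T:<b>.<level>`.
#' @export
toy_ontology <- function(n_branches, depth = 3) {
  stopifnot(n_branches >= 1, depth >= 1)
  root <- "T:root"
  terms <- root
  parents <- list()
  for (b in seq_len(n_branches)) {
    chain <- sprintf("T:%d.%d", b, seq_len(depth))
    terms <- c(terms, chain)
    parents[[chain[1L]]] <- root
    if (depth > 1) {
      for (k in 2:depth) parents[[chain[k]]] <- chain[k - 1L]
    }
  }
  ontology(terms, parents)
}

rnorm_clamped <- function(n, mean, sd, lo = 0, hi = 1) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic benchmarking world with planted function clusters
#'
#' Builds a complete, self-contained test universe: proteins assigned to
#' latent function clusters, a toy ontology with one branch per cluster, true
#' (propagation-consistent) annotation sets and EC numbers per cluster, and a
#' pair table whose TM and SNN scores are drawn from a high-mode distribution
#' for same-cluster pairs and a low-mode distribution otherwise, emulating
#' the separation of sibling pairs in TM x SNN space. The generator's
#' bookkeeping (`same_cluster`) is the exact ground truth that the sibling
#' gate is measured against.
#'
#' Defaults yield roughly 2-3% gate-positive pairs under the standard gate
#' (TM >= 0.7, SNN >= 0.98), with ~90% of sibling pairs under 40% sequence
#' identity. Setting the same/other score modes far apart (e.g.
#' `tm_sib = c(0.9, 0.02)`, `tm_other = c(0.4, 0.05)`, and likewise for SNN)
#' gives fully separated modes where the gate recovers the planted clusters
#' exactly.
#'
#' @param n_proteins total proteins (default 200); must be at least
#'   `2 * n_clusters`.
#' @param n_clusters number of planted function clusters (default 20, >= 2).
#' @param seed integer master seed; all randomness derives from it.
#' @param ont_depth depth of each ontology branch (default 3).
#' @param tm_sib,tm_other,snn_sib,snn_other length-2 numeric `c(mean, sd)` of
#'   the clamped-normal score distributions for same-cluster and
#'   cross-cluster pairs.
#' @param id_sib,id_other length-2 `c(shape1, shape2)` of the Beta
#'   distributions (scaled to 0-90%) for pair sequence identity.
#' @return An object of class `fp_world`: list with `proteins` (metadata
#'   data.frame), `ontology`, `annotations` (true propagated term sets),
#'   `ec` (true EC number per protein), `pairs` (all unordered pairs with
#'   `tm`, `snn`, `identity`, `same_cluster`), `params`, `seed`.
#' @export
generate_world <- function(n_proteins = 200, n_clusters = 20, seed = 1,
                           ont_depth = 3,
                           tm_sib = c(0.82, 0.10), tm_other = c(0.45, 0.12),
                           snn_sib = c(0.985, 0.012), snn_other = c(0.55, 0.18),
                           id_sib = c(2, 8), id_other = c(1.2, 15)) {
  stopifnot(n_clusters >= 2, n_proteins >= 2 * n_clusters)
  params <- list(n_proteins = n_proteins, n_clusters = n_clusters,
                 ont_depth = ont_depth, tm_sib = tm_sib, tm_other = tm_other,
                 snn_sib = snn_sib, snn_other = snn_other,
                 id_sib = id_sib, id_other = id_other)
  local_seed(seed, {
    ids <- sprintf("P%04d", seq_len(n_proteins))
    cluster <- sort(rep_len(seq_len(n_clusters), n_proteins))
    dag <- toy_ontology(n_clusters, depth = ont_depth)
    # cluster k is annotated with the full chain of branch k
    cluster_terms <- lapply(seq_len(n_clusters), function(b) {
      propagate(dag, sprintf("T:%d.%d", b, ont_depth))
    })
    ec1 <- sample(1:6, n_clusters, replace = TRUE)
    cluster_ec <- sprintf("%d.%d.%d.1", ec1, seq_len(n_clusters),
                          sample(1:9, n_clusters, replace = TRUE))
    proteins <- data.frame(
      protein = ids, cluster = cluster,
      length = sample(80:400, n_proteins, replace = TRUE),
      identity = stats::runif(n_proteins, 2, 29.5),
      plddt = stats::runif(n_proteins, 0.905, 1),
      ptm = stats::runif(n_proteins, 0.905, 1),
      stringsAsFactors = FALSE)
    ij <- utils::combn(n_proteins, 2L)
    same <- cluster[ij[1L, ]] == cluster[ij[2L, ]]
    n_pair <- ncol(ij)
    draw <- function(flag, par_yes, par_no, betas = FALSE) {
      out <- numeric(n_pair)
      if (betas) {
        out[flag] <- 90 * stats::rbeta(sum(flag), par_yes[1L], par_yes[2L])
        out[!flag] <- 90 * stats::rbeta(sum(!flag), par_no[1L], par_no[2L])
      } else {
        out[flag] <- rnorm_clamped(sum(flag), par_yes[1L], par_yes[2L])
        out[!flag] <- rnorm_clamped(sum(!flag), par_no[1L], par_no[2L])
      }
      out
    }
    pairs <- data.frame(
      id1 = ids[ij[1L, ]], id2 = ids[ij[2L, ]],
      tm = draw(same, tm_sib, tm_other),
      snn = draw(same, snn_sib, snn_other),
      identity = draw(same, id_sib, id_other, betas = TRUE),
      same_cluster = same,
      stringsAsFactors = FALSE)
    structure(list(
      proteins = proteins,
      ontology = dag,
      annotations = stats::setNames(cluster_terms[cluster], ids),
      ec = stats::setNames(as.list(cluster_ec[cluster]), ids),
      pairs = pairs,
      params = params, seed = seed
    ), class = "fp_world")
  })
}

#' @export
print.fp_world <- function(x, ...) {
  cat("Synthetic world:", nrow(x$proteins), "proteins in",
      x$params$n_clusters, "clusters;", nrow(x$pairs), "pairs (",
      sum(x$pairs$same_cluster), "same-cluster) | seed", x$seed, "\n")
  invisible(x)
}

#' Simulate an annotation predictor of controllable fidelity
#'
#' Starts from the world's true annotations and degrades them: each true term
#' is dropped with probability `dropout`; each foreign vocabulary term is
#' added with probability `spurious`; whole proteins are removed with
#' probability `1 - coverage`. Confidence scores are a calibrated truth
#' indicator (`true_score` for true terms, `spurious_score` for added ones)
#' plus Gaussian noise of standard deviation `noise`.
#'
#' @param world an `fp_world`.
#' @param dropout,spurious,noise,coverage fidelity dials, rates in \[0,1\]
#'   (`noise` is a standard deviation, >= 0).
#' @param seed integer seed.
#' @param source annotate with ontology `"terms"` (default) or true `"ec"`
#'   numbers (spurious draws then come from other clusters' EC numbers).
#' @param true_score,spurious_score score baselines before noise.
#' @param method method name for reports.
#' @return An `fp_predictions` table (vocabulary `"custom"` or `"EC"`).
#' @export
simulate_predictor <- function(world, dropout = 0, spurious = 0, noise = 0,
                               coverage = 1, seed = 1,
                               source = c("terms", "ec"),
                               true_score = 0.9, spurious_score = 0.3,
                               method = NULL) {
  stopifnot(inherits(world, "fp_world"),
            dropout >= 0, dropout <= 1, spurious >= 0, spurious <= 1,
            coverage >= 0, coverage <= 1, noise >= 0)
  source <- match.arg(source)
  truth <- if (source == "terms") world$annotations else world$ec
  vocab_all <- unique(unlist(truth, use.names = FALSE))
  local_seed(seed, {
    keep <- stats::runif(length(truth)) <= coverage
    rows <- lapply(names(truth)[keep], function(pid) {
      tset <- truth[[pid]]
      kept <- tset[stats::runif(length(tset)) > dropout]
      foreign <- setdiff(vocab_all, tset)
      added <- foreign[stats::runif(length(foreign)) < spurious]
      if (!length(kept) && !length(added)) return(NULL)
      data.frame(protein = pid,
                 term = c(kept, added),
                 truth = rep(c(TRUE, FALSE), c(length(kept), length(added))),
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows)) {
      stop("simulated predictor annotated no protein (dropout/coverage too",
           " extreme)")
    }
    df <- do.call(rbind, rows)
    score <- ifelse(df$truth, true_score, spurious_score)
    if (noise > 0) score <- score + stats::rnorm(nrow(df), 0, noise)
    prediction_table(df$protein, df$term, score,
                     vocabulary = if (source == "ec") "EC" else "custom",
                     orientation = "higher",
                     method = method %||% sprintf(
                       "sim(d=%g,s=%g,n=%g,c=%g)", dropout, spurious, noise,
                       coverage))
  })
}

#' Simulate per-protein embeddings with cluster structure
#'
#' Cluster centroids are drawn i.i.d. Gaussian at the between-cluster scale;
#' each protein's vector is its cluster centroid plus Gaussian noise at the
#' within-cluster scale. As the within/between ratio shrinks, same-cluster
#' cosine similarity approaches 1.
#'
#' @param world an `fp_world`.
#' @param dim embedding dimension (>= 2, default 16).
#' @param within_sd,between_sd positive noise scales (defaults 0.5 and 2).
#' @param seed integer seed.
#' @return Numeric matrix, one row per protein (rownames = protein IDs).
#' @export
simulate_embeddings <- function(world, dim = 16, within_sd = 0.5,
                                between_sd = 2, seed = 1) {
  stopifnot(inherits(world, "fp_world"), dim >= 2,
            within_sd > 0, between_sd > 0)
  local_seed(seed, {
    k <- world$params$n_clusters
    centroids <- matrix(stats::rnorm(k * dim, 0, between_sd), nrow = k)
    emb <- centroids[world$proteins$cluster, , drop = FALSE] +
      matrix(stats::rnorm(nrow(world$proteins) * dim, 0, within_sd),
             ncol = dim)
    rownames(emb) <- world$proteins$protein
    emb
  })
}
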