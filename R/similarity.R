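#' Set-based similarity kernels
#'
#' Convert two proteins' predicted annotation term sets into a similarity
#' score S in \[0,1\].
#'
#' * `jaccard_similarity`: |intersection| / |union|.
#' * `ia_weighted_jaccard`: Jaccard with terms weighted by information
#'   accretion, computed on ancestor-propagated sets (roots removed):
#'   `sum(Ia over intersection) / sum(Ia over union)`. With uniform Ia this
#'   reduces exactly to the unweighted Jaccard.
#' * `binary_shared`: 1 if the sets share at least one term, else 0 — the
#'   rule used for EC/Pfam/ortholog vocabularies when any common annotation
#'   counts as shared function.
#'
#' @param set1,set2 character term sets; must be non-empty (callers exclude
#'   unannotated proteins).
#' @param ia named numeric vector of information-accretion weights
#'   (see [compute_information_accretion()]).
#' @param dag an `fp_ontology` used to propagate the sets before weighting.
#' @return A similarity in \[0,1\]; `ia_weighted_jaccard` returns `NA` with a
#'   warning when the union carries zero Ia mass (pair excluded by callers).
#' @export
jaccard_similarity <- function(set1, set2) {
  if (!length(set1) || !length(set2)) stop("Jaccard undefined for empty sets")
  set1 <- unique(set1); set2 <- unique(set2)
  ni <- sum(set1 %in% set2)
  ni / (length(set1) + length(set2) - ni)
}

#' @rdname jaccard_similarity
#' @export
ia_weighted_jaccard <- function(set1, set2, ia, dag = NULL) {
  if (!length(set1) || !length(set2)) stop("similarity undefined for empty sets")
  if (!is.null(dag)) {
    set1 <- propagate(dag, set1)
    set2 <- propagate(dag, set2)
    if (!length(set1) || !length(set2)) {
      warning("annotation set reduced to roots only; pair excluded")
      return(NA_real_)
    }
  }
  u <- union(set1, set2)
  unknown <- setdiff(u, names(ia))
  if (length(unknown)) {
    stop("no information-accretion value for term(s): ",
         paste(unknown, collapse = ", "))
  }
  denom <- sum(ia[u])
  if (denom == 0) {
    warning("zero information-accretion mass in union; pair excluded")
    return(NA_real_)
  }
  sum(ia[intersect(set1, set2)]) / denom
}

#' @rdname jaccard_similarity
#' @export
binary_shared <- function(set1, set2) {
  if (!length(set1) || !length(set2)) stop("similarity undefined for empty sets")
  as.numeric(length(intersect(set1, set2)) > 0L)
}

#' Embedding-based similarity kernels
#'
#' `euclidean_similarity` maps the Euclidean distance d between two embedding
#' vectors into (0,1\]: `S = 0.5 / (0.5 + d/2)`, so identical vectors score 1
#' and S decays to 0 as d grows. The `"sqrt_half"` variant uses
#' `S = 0.5 / (0.5 + sqrt(sum(diff^2)/2))` instead.
#'
#' `cosine_similarity` L2-normalizes both vectors and maps the cosine into
#' \[0,1\]: `S = (e1 . e2 + 1) / 2`.
#'
#' @param e1,e2 numeric vectors of equal length (non-zero for cosine).
#' @param variant denominator convention for the Euclidean kernel.
#' @return A similarity in \[0,1\].
#' @export
euclidean_similarity <- function(e1, e2,
                                 variant = c("half_distance", "sqrt_half")) {
  variant <- match.arg(variant)
  if (length(e1) != length(e2)) stop("embedding length mismatch")
  d2 <- sum((e1 - e2)^2)
  denom <- switch(variant,
                  half_distance = sqrt(d2) / 2,
                  sqrt_half = sqrt(d2 / 2))
  0.5 / (0.5 + denom)
}

#' @rdname euclidean_similarity
#' @export
cosine_similarity <- function(e1, e2) {
  if (length(e1) != length(e2)) stop("embedding length mismatch")
  n1 <- sqrt(sum(e1^2)); n2 <- sqrt(sum(e2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity undefined for zero vector")
  s <- (sum((e1 / n1) * (e2 / n2)) + 1) / 2
  min(max(s, 0), 1)
}

#' Score a pair table with a similarity kernel
#'
#' Computes S for every pair whose two proteins are available to the kernel:
#' annotated (set kernels) or embedded (vector kernels). For EC vocabularies
#' give `ec_level` to truncate codes before set comparison.
#'
#' @param pairs data.frame with `id1`, `id2` columns.
#' @param sets an `fp_annotation_sets` (set kernels).
#' @param embeddings numeric matrix, one row per protein, rownames = protein
#'   IDs (vector kernels).
#' @param kernel one of `"jaccard"`, `"ia_jaccard"`, `"binary_shared"`,
#'   `"euclidean"`, `"cosine"`.
#' @param ia,dag required for `kernel = "ia_jaccard"`.
#' @param ec_level optional EC truncation level applied to the sets first.
#' @param euclidean_variant passed to [euclidean_similarity()].
#' @return data.frame `id1`, `id2`, `S` over the scoreable pairs (pairs whose
#'   weighted similarity is undefined are dropped with the kernel's warning).
#' @export
pair_scores <- function(pairs, sets = NULL, embeddings = NULL,
                        kernel = c("jaccard", "ia_jaccard", "binary_shared",
                                   "euclidean", "cosine"),
                        ia = NULL, dag = NULL, ec_level = NULL,
                        euclidean_variant = "half_distance") {
  kernel <- match.arg(kernel)
  if (kernel %in% c("euclidean", "cosine")) {
    stopifnot(is.matrix(embeddings), !is.null(rownames(embeddings)))
    keep <- pairs$id1 %in% rownames(embeddings) &
      pairs$id2 %in% rownames(embeddings)
    out <- pairs[keep, c("id1", "id2"), drop = FALSE]
    fun <- if (kernel == "cosine") cosine_similarity else
      function(a, b) euclidean_similarity(a, b, variant = euclidean_variant)
    out$S <- mapply(function(a, b) fun(embeddings[a, ], embeddings[b, ]),
                    out$id1, out$id2, USE.NAMES = FALSE)
  } else {
    stopifnot(!is.null(sets))
    if (!is.null(ec_level)) {
      sets <- lapply(sets, function(s) {
        t <- truncate_ec(s, ec_level)
        unique(t[!is.na(t)])
      })
      sets <- sets[vapply(sets, length, 1L) > 0L]
    }
    if (kernel == "ia_jaccard" && !is.null(dag)) {
      # propagate once per protein, not per pair
      sets <- lapply(sets, function(s) propagate(dag, s))
      sets <- sets[vapply(sets, length, 1L) > 0L]
      dag <- NULL
    }
    keep <- pairs$id1 %in% names(sets) & pairs$id2 %in% names(sets)
    out <- pairs[keep, c("id1", "id2"), drop = FALSE]
    out$S <- set_kernel_scores(sets, out$id1, out$id2, kernel, ia)
    if (anyNA(out$S)) {
      warning(sum(is.na(out$S)),
              " pair(s) with zero information-accretion mass excluded")
      out <- out[!is.na(out$S), , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

# Vectorized set-kernel scores over many pairs via a protein x term incidence
# matrix (falls back to the per-pair kernels when that matrix would be huge).
# For ia_jaccard the sets are assumed already propagated; `ia` must cover
# every term in use. Returns NA where the weighted union mass is zero.
set_kernel_scores <- function(sets, id1, id2, kernel, ia = NULL) {
  if (!length(id1)) return(numeric(0))
  prots <- unique(c(id1, id2))
  terms_all <- unique(unlist(sets[prots], use.names = FALSE))
  if (length(prots) * length(terms_all) > 2e7) {
    fun <- switch(kernel,
                  jaccard = jaccard_similarity,
                  binary_shared = binary_shared,
                  ia_jaccard = function(a, b) ia_weighted_jaccard(a, b, ia))
    return(suppressWarnings(
      mapply(function(a, b) fun(sets[[a]], sets[[b]]), id1, id2,
             USE.NAMES = FALSE)))
  }
  m <- matrix(FALSE, length(prots), length(terms_all),
              dimnames = list(prots, terms_all))
  for (p in prots) m[p, sets[[p]]] <- TRUE
  m1 <- m[id1, , drop = FALSE]
  m2 <- m[id2, , drop = FALSE]
  if (kernel == "ia_jaccard") {
    unknown <- setdiff(terms_all, names(ia))
    if (length(unknown)) {
      stop("no information-accretion value for term(s): ",
           paste(unknown, collapse = ", "))
    }
    w <- ia[terms_all]
    inter <- as.vector((m1 & m2) %*% w)
    uni <- as.vector((m1 | m2) %*% w)
    ifelse(uni == 0, NA_real_, inter / uni)
  } else {
    inter <- rowSums(m1 & m2)
    if (kernel == "binary_shared") as.numeric(inter > 0) else
      inter / (rowSums(m1) + rowSums(m2) - inter)
  }
}
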