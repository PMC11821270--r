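#' Construct an ontology DAG
#'
#' Builds the directed acyclic term graph used for annotation propagation and
#' information-accretion estimation. Edges point child -> parent; roots are
#' the terms with no parents.
#'
#' @param terms character vector of term identifiers.
#' @param parents named list mapping a child term to the character vector of
#'   its parent terms. Terms absent from the list (or mapped to
#'   `character(0)`) are roots.
#' @param namespace optional named character vector tagging each term with a
#'   namespace (e.g. `"molecular_function"`).
#' @return An object of class `fp_ontology` with elements `terms`, `parents`
#'   (complete, one entry per term), `roots` and `namespace`.
#' @details The constructor verifies that every parent is a known term and
#'   that the graph is acyclic (Kahn topological sort); a cycle is a hard
#'   error naming one member of the cycle.
#' @seealso [parse_obo()], [propagate()], [compute_information_accretion()]
#' @export
ontology <- function(terms, parents = list(), namespace = NULL) {
  terms <- unique(as.character(terms))
  full <- stats::setNames(vector("list", length(terms)), terms)
  for (tm in terms) full[[tm]] <- character(0)
  for (child in names(parents)) {
    if (!child %in% terms) {
      stop("parent map refers to unknown term: ", child)
    }
    p <- unique(as.character(parents[[child]]))
    if (length(p) && !all(p %in% terms)) {
      stop("unknown parent term(s): ",
           paste(setdiff(p, terms), collapse = ", "))
    }
    if (child %in% p) stop("cycle detected involving term: ", child)
    full[[child]] <- p
  }
  roots <- terms[vapply(full, length, 1L) == 0L]
  if (length(terms) && !length(roots)) {
    stop("cycle detected involving term: ", terms[[1L]])
  }
  .check_acyclic(terms, full)
  structure(
    list(terms = terms, parents = full, roots = roots, namespace = namespace),
    class = "fp_ontology"
  )
}

# Kahn's algorithm; stops naming a cycle member if not all terms are sorted.
.check_acyclic <- function(terms, parents) {
  indeg <- stats::setNames(integer(length(terms)), terms)
  for (child in names(parents)) {
    for (p in parents[[child]]) indeg[[p]] <- indeg[[p]] + 1L
  }
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (p in parents[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(terms)) {
    stop("cycle detected involving term: ", names(indeg)[indeg > 0L][[1L]])
  }
  invisible(TRUE)
}

#' @export
print.fp_ontology <- function(x, ...) {
  cat("Ontology DAG:", length(x$terms), "terms,",
      length(x$roots), "root(s)\n")
  invisible(x)
}

#' Parse an OBO flat file into an ontology DAG
#'
#' Reads a GO-release-style OBO file. Only `[Term]` stanzas are used;
#' obsolete terms are excluded. Child -> parent edges are taken from `is_a`
#' lines and, optionally, from `relationship: part_of` lines.
#'
#' @param path path to an OBO file.
#' @param use_part_of logical; also treat `part_of` relationships as
#'   propagation edges (default `FALSE`, `is_a` only).
#' @return An `fp_ontology`.
#' @export
parse_obo <- function(path, use_part_of = FALSE) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- grep("^\\[", lines)
  terms <- character(0)
  parents <- list()
  namespace <- character(0)
  obsolete <- character(0)
  edge_to <- character(0)  # referenced parents, may lack own stanza
  bounds <- c(stanza_starts, length(lines) + 1L)
  for (i in seq_along(stanza_starts)) {
    block <- lines[stanza_starts[i]:(bounds[i + 1L] - 1L)]
    if (!identical(block[[1L]], "[Term]")) next
    id <- sub("^id: *", "", grep("^id: ", block, value = TRUE))
    if (length(id) != 1L) next
    id <- sub(" *!.*$", "", id)
    if (any(grepl("^is_obsolete: *true", block))) {
      obsolete <- c(obsolete, id)
      next
    }
    isa <- sub("^is_a: *", "", grep("^is_a: ", block, value = TRUE))
    isa <- trimws(sub(" *(!|\\{).*$", "", isa))
    if (use_part_of) {
      po <- grep("^relationship: *part_of ", block, value = TRUE)
      po <- trimws(sub(" *(!|\\{).*$", "",
                       sub("^relationship: *part_of *", "", po)))
      isa <- c(isa, po)
    }
    ns <- sub("^namespace: *", "", grep("^namespace: ", block, value = TRUE))
    terms <- c(terms, id)
    parents[[id]] <- isa
    edge_to <- c(edge_to, isa)
    namespace[[id]] <- if (length(ns)) ns[[1L]] else NA_character_
  }
  if (!length(terms)) stop("no usable [Term] stanzas in: ", path)
  # drop edges into obsolete or undeclared parents rather than invent terms
  keep <- terms
  parents <- lapply(parents, function(p) intersect(p, keep))
  ontology(terms, parents, namespace = namespace)
}

#' Ancestor-closure propagation of an annotation set
#'
#' Expands a term set to include all ancestors reachable through the DAG's
#' child -> parent edges. Root terms are removed from the result by default:
#' they are shared by every annotated protein, carry zero information
#' accretion, and would only inflate similarity denominators.
#'
#' @param dag an `fp_ontology`.
#' @param terms character vector of term identifiers; all must exist in `dag`.
#' @param drop_roots remove root terms from the closure (default `TRUE`).
#' @return Character vector: the input terms plus all their ancestors
#'   (roots excluded unless `drop_roots = FALSE`). Idempotent.
#' @export
propagate <- function(dag, terms, drop_roots = TRUE) {
  stopifnot(inherits(dag, "fp_ontology"))
  terms <- unique(as.character(terms))
  if (!length(terms)) return(character(0))
  unknown <- setdiff(terms, dag$terms)
  if (length(unknown)) {
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  }
  out <- character(0)
  frontier <- terms
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- setdiff(
      unique(unlist(dag$parents[frontier], use.names = FALSE)), out)
  }
  out <- unique(out)
  if (drop_roots) out <- setdiff(out, dag$roots)
  sort(out)
}

#' Estimate per-term information accretion from an annotation corpus
#'
#' Information accretion of a term v is the information gained by adding v to
#' its parents: `Ia(v) = -log2 Pr(v | Parents(v))`, with the conditional
#' probability estimated by corpus counts. Smoothing `alpha` is added to both
#' numerator and denominator so terms unseen in the corpus get finite Ia;
#' `alpha = 0` gives the exact plug-in estimate (and may yield `Inf`).
#'
#' Corpus sets are expected to be ancestor-propagated with roots removed (the
#' output of [propagate()]); root parents are therefore treated as present in
#' every protein, and roots themselves receive `Ia = 0`.
#'
#' @param dag an `fp_ontology`.
#' @param corpus named list: protein ID -> propagated character term set.
#' @param alpha smoothing constant (default 1).
#' @return Named numeric vector of non-negative Ia values (bits), one per
#'   term in `dag`.
#' @export
compute_information_accretion <- function(dag, corpus, alpha = 1) {
  stopifnot(inherits(dag, "fp_ontology"))
  if (!length(corpus)) stop("empty annotation corpus")
  stopifnot(alpha >= 0)
  ia <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  nonroot <- setdiff(dag$terms, dag$roots)
  for (v in nonroot) {
    pars <- setdiff(dag$parents[[v]], dag$roots)
    if (length(pars)) {
      has_par <- vapply(corpus, function(s) all(pars %in% s), TRUE)
    } else {
      has_par <- rep(TRUE, length(corpus))  # only root parents: universal
    }
    has_v <- vapply(corpus, function(s) v %in% s, TRUE)
    n_par <- sum(has_par)
    n_both <- sum(has_par & has_v)
    pr <- (n_both + alpha) / (n_par + alpha)
    ia[[v]] <- -log2(pr)
  }
  ia
}

# ---- EC numbers -------------------------------------------------------------

#' Parse an EC number string
#'
#' Accepts up to four dot-separated positions, each a digit string or the
#' missing marker `-`; trailing positions may be absent and are treated as
#' missing. A missing position implies all deeper positions are missing.
#'
#' @param ec character vector of EC strings, e.g. `"1.2.3.4"`, `"2.7.-.-"`.
#' @return A character matrix with 4 columns (one row per input), `NA` for
#'   missing positions.
#' @export
parse_ec <- function(ec) {
  ec <- as.character(ec)
  out <- matrix(NA_character_, nrow = length(ec), ncol = 4L)
  for (i in seq_along(ec)) {
    parts <- strsplit(trimws(ec[[i]]), ".", fixed = TRUE)[[1L]]
    if (!length(parts) || length(parts) > 4L ||
        !all(grepl("^([0-9]+|-)$", parts))) {
      stop("malformed EC number: '", ec[[i]], "'")
    }
    parts[parts == "-"] <- NA_character_
    # a gap may not be followed by a filled position
    if (any(is.na(parts)) &&
        any(!is.na(parts[seq(which(is.na(parts))[1L], length(parts))]))) {
      stop("malformed EC number (digit after missing position): '",
           ec[[i]], "'")
    }
    out[i, seq_along(parts)] <- parts
  }
  out
}

#' Truncate EC numbers to a hierarchy level
#'
#' `"1.2.3.4"` at level 3 becomes `"1.2.3"`. If any of the first `level`
#' positions is missing, the code is incomplete at that level and the result
#' is `NA`, which never compares equal to anything.
#'
#' @param ec character vector of EC strings.
#' @param level integer in 1..4.
#' @return Character vector of truncated codes (`NA` where incomplete).
#' @export
truncate_ec <- function(ec, level) {
  stopifnot(length(level) == 1L, level %in% 1:4)
  m <- parse_ec(ec)
  m <- m[, seq_len(level), drop = FALSE]
  ok <- rowSums(is.na(m)) == 0L
  out <- rep(NA_character_, nrow(m))
  out[ok] <- apply(m[ok, , drop = FALSE], 1L, paste, collapse = ".")
  out
}
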