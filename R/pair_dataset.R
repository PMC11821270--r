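#' Apply the orphan-protein filters
#'
#' Keeps proteins that look like well-modeled orphans: sequence identity to
#' the reference database strictly below `id_max` percent, length at most
#' `len_max` residues, and both structure-confidence scores (pLDDT, pTM)
#' strictly above their minima. If a logical `truncated` column is present,
#' truncated records are dropped as well.
#'
#' @param records data.frame with columns `protein`, `length`, `identity`
#'   (percent in \[0,100\]), `plddt`, `ptm` (each in \[0,1\]).
#' @param id_max identity cutoff, percent; strict `<` (default 30).
#' @param len_max maximum length in residues, inclusive (default 400:
#'   proteins over 400 residues are dropped).
#' @param plddt_min,ptm_min strict `>` cutoffs (default 0.9).
#' @return The filtered data.frame.
#' @export
filter_orphans <- function(records, id_max = 30, len_max = 400,
                           plddt_min = 0.9, ptm_min = 0.9) {
  need <- c("protein", "length", "identity", "plddt", "ptm")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in need[-1L]) {
    if (any(is.na(records[[col]]))) {
      stop("missing ", col, " for protein(s): ",
           paste(utils::head(records$protein[is.na(records[[col]])], 3L),
                 collapse = ", "))
    }
  }
  stopifnot(all(records$length >= 1),
            all(records$identity >= 0 & records$identity <= 100),
            all(records$plddt >= 0 & records$plddt <= 1),
            all(records$ptm >= 0 & records$ptm <= 1))
  keep <- records$identity < id_max & records$length <= len_max &
    records$plddt > plddt_min & records$ptm > ptm_min
  if ("truncated" %in% names(records)) keep <- keep & !records$truncated
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract protein IDs and lengths from a FASTA file
#'
#' Convenience intake for building metadata tables: returns the sequence
#' identifiers (first whitespace-delimited token of each header) and lengths.
#'
#' @param path FASTA file (protein or nucleotide).
#' @return data.frame with columns `protein`, `length`.
#' @export
fasta_lengths <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("fasta_lengths() needs the Biostrings package")
  }
  len <- Biostrings::fasta.seqlengths(path)
  data.frame(protein = sub("\\s.*$", "", names(len)),
             length = unname(len), stringsAsFactors = FALSE)
}

#' Label sibling pairs with the SNN+TM gate
#'
#' A pair is labeled `sibling` when both gates pass: TM score at least
#' `tm_min` and SNN score at least `snn_min` (both inclusive). Everything
#' else is `unlabeled` — a mixture dominated by non-siblings, treated as
#' negatives downstream (positive-versus-unlabeled design).
#'
#' @param pairs data.frame with columns `id1`, `id2`, `tm`, `snn` and
#'   optionally `identity` (percent).
#' @param tm_min,snn_min gate thresholds in \[0,1\] (defaults 0.7 and 0.98).
#' @return An object of class `fp_pair_dataset`: the canonicalized pair table
#'   with a `label` factor and attributes `tm_min`, `snn_min`, `n_sibling`,
#'   `n_unlabeled`.
#' @export
label_siblings <- function(pairs, tm_min = 0.7, snn_min = 0.98) {
  stopifnot(is.data.frame(pairs),
            all(c("id1", "id2", "tm", "snn") %in% names(pairs)),
            tm_min >= 0, tm_min <= 1, snn_min >= 0, snn_min <= 1)
  if (any(pairs$tm < 0 | pairs$tm > 1 | pairs$snn < 0 | pairs$snn > 1,
          na.rm = FALSE)) {
    stop("TM/SNN scores must lie in [0,1]")
  }
  pairs <- canonicalize_pairs(pairs)
  lab <- ifelse(pairs$tm >= tm_min & pairs$snn >= snn_min,
                "sibling", "unlabeled")
  pairs$label <- factor(lab, levels = c("sibling", "unlabeled"))
  structure(pairs, class = c("fp_pair_dataset", "data.frame"),
            tm_min = tm_min, snn_min = snn_min,
            n_sibling = sum(lab == "sibling"),
            n_unlabeled = sum(lab == "unlabeled"))
}

#' Canonicalize a pair table
#'
#' Orders each pair lexicographically (`id1 < id2`), rejects self-pairs and
#' errors on duplicated unordered pairs.
#'
#' @param pairs data.frame with `id1`, `id2` columns.
#' @return The reordered data.frame.
#' @export
canonicalize_pairs <- function(pairs) {
  id1 <- as.character(pairs$id1); id2 <- as.character(pairs$id2)
  if (any(id1 == id2)) {
    stop("self-pair(s) not allowed: ", id1[id1 == id2][1L])
  }
  swap <- id1 > id2
  pairs$id1 <- ifelse(swap, id2, id1)
  pairs$id2 <- ifelse(swap, id1, id2)
  key <- paste(pairs$id1, pairs$id2)
  if (anyDuplicated(key)) {
    stop("duplicated unordered pair: ", key[duplicated(key)][1L])
  }
  rownames(pairs) <- NULL
  pairs
}

#' @export
print.fp_pair_dataset <- function(x, ...) {
  cat("Pair dataset:", nrow(x), "pairs |",
      attr(x, "n_sibling"), "siblings,",
      attr(x, "n_unlabeled"), "unlabeled",
      sprintf("(gate TM >= %g, SNN >= %g)\n",
              attr(x, "tm_min"), attr(x, "snn_min")))
  invisible(x)
}

#' Balanced under-sampling of unlabeled pairs
#'
#' Retains all sibling pairs and samples, without replacement, an equal
#' number of unlabeled pairs. Deterministic given `seed`.
#'
#' @param dataset an `fp_pair_dataset`.
#' @param seed integer seed for the sample.
#' @return A balanced `fp_pair_dataset` (same attributes, updated counts).
#' @export
undersample_balanced <- function(dataset, seed) {
  stopifnot(inherits(dataset, "fp_pair_dataset"))
  sib <- which(dataset$label == "sibling")
  unl <- which(dataset$label == "unlabeled")
  if (length(unl) < length(sib)) {
    stop("fewer unlabeled (", length(unl), ") than sibling (", length(sib),
         ") pairs: balanced under-sampling is degenerate")
  }
  if (!length(sib)) stop("no sibling pairs to balance against")
  take <- unl[local_seed(seed, sample.int(length(unl), length(sib)))]
  out <- dataset[sort(c(sib, take)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(dataset),
            tm_min = attr(dataset, "tm_min"), snn_min = attr(dataset, "snn_min"),
            n_sibling = length(sib), n_unlabeled = length(sib))
}

# run expr under a temporary RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Binary same-function labels from EC numbers
#'
#' Two proteins carry the same function at a given EC level when their
#' truncated EC sets intersect. Codes incomplete at that level are dropped;
#' pairs with a protein lacking any (complete) EC annotation are skipped with
#' a warning.
#'
#' @param annotations named list: protein -> character vector of EC strings.
#' @param pairs data.frame with `id1`, `id2`.
#' @param level EC hierarchy level in 1..4 (default 3).
#' @return data.frame `id1`, `id2`, `same` (logical), covering the pairs that
#'   could be compared.
#' @export
binary_ec_labels <- function(annotations, pairs, level = 3) {
  trunc_sets <- lapply(annotations, function(ecs) {
    out <- truncate_ec(ecs, level)
    unique(out[!is.na(out)])
  })
  trunc_sets <- trunc_sets[vapply(trunc_sets, length, 1L) > 0L]
  ok <- pairs$id1 %in% names(trunc_sets) & pairs$id2 %in% names(trunc_sets)
  if (any(!ok)) {
    warning(sum(!ok), " pair(s) skipped: protein without EC annotation ",
            "complete at level ", level)
  }
  kept <- pairs[ok, c("id1", "id2"), drop = FALSE]
  kept$same <- mapply(function(a, b) {
    length(intersect(trunc_sets[[a]], trunc_sets[[b]])) > 0L
  }, kept$id1, kept$id2, USE.NAMES = FALSE)
  rownames(kept) <- NULL
  kept
}
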