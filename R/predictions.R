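#' Create a prediction table
#'
#' In-memory constructor for per-protein, per-term annotation predictions of
#' one method/vocabulary. Raw scores are normalized to an internal
#' higher-is-better scale: for `orientation = "lower"` (e.g. E-values) the
#' internal score is `-log10(raw)`, with zero raw values floored at
#' `zero_cap`. Duplicate (protein, term) rows collapse to the best internal
#' score.
#'
#' @param protein,term character vectors (recycled to common length).
#' @param score numeric raw scores; must be finite (zero allowed for
#'   lower-is-better scores).
#' @param vocabulary one of `"GO"`, `"EC"`, `"Pfam"`, `"KO"`, `"COG"`,
#'   `"custom"`.
#' @param orientation `"higher"` if larger raw scores are more confident,
#'   `"lower"` for E-value-like scores.
#' @param zero_cap internal score assigned to a raw value of 0 under
#'   `orientation = "lower"` (default 300).
#' @param method optional method name carried into reports.
#' @return An object of class `fp_predictions`: a data.frame with columns
#'   `protein`, `term`, `raw`, `score` (internal) and attributes
#'   `vocabulary`, `orientation`, `method`.
#' @export
prediction_table <- function(protein, term, score,
                             vocabulary = c("custom", "GO", "EC", "Pfam",
                                            "KO", "COG"),
                             orientation = c("higher", "lower"),
                             zero_cap = 300, method = "method") {
  vocabulary <- match.arg(vocabulary)
  orientation <- match.arg(orientation)
  df <- data.frame(protein = as.character(protein),
                   term = as.character(term),
                   raw = as.numeric(score),
                   stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty prediction table")
  if (any(!is.finite(df$raw))) stop("non-finite prediction score(s)")
  if (orientation == "lower") {
    if (any(df$raw < 0)) stop("negative score under lower-is-better orientation")
    df$score <- ifelse(df$raw == 0, zero_cap, -log10(df$raw))
    df$score <- pmin(df$score, zero_cap)
  } else {
    df$score <- df$raw
  }
  # collapse duplicates, keeping the best internal score
  o <- order(df$protein, df$term, -df$score)
  df <- df[o, , drop = FALSE]
  df <- df[!duplicated(df[c("protein", "term")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("fp_predictions", "data.frame"),
            vocabulary = vocabulary, orientation = orientation,
            method = method)
}

#' Load a prediction table from a delimited file
#'
#' Reads a CAFA-style table (protein, term, score, optionally vocabulary) in
#' tab-separated text and normalizes it via [prediction_table()].
#'
#' @param path file path.
#' @param columns named integer or character vector locating the `protein`,
#'   `term` and `score` columns (default the first three).
#' @param vocabulary,orientation,zero_cap,method see [prediction_table()].
#' @param header logical, passed to [utils::read.delim()].
#' @inherit prediction_table return
#' @export
load_predictions <- function(path, columns = c(protein = 1, term = 2, score = 3),
                             vocabulary = "custom",
                             orientation = c("higher", "lower"),
                             zero_cap = 300, method = NULL, header = TRUE) {
  if (!file.exists(path)) stop("cannot read prediction file: ", path)
  raw <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (!nrow(raw)) stop("empty prediction file: ", path)
  get <- function(key) raw[[columns[[key]]]]
  sc <- get("score")
  if (!is.numeric(sc)) {
    bad <- which(is.na(suppressWarnings(as.numeric(sc))))[1L]
    stop("non-numeric score at data row ", bad, " of ", path)
  }
  prediction_table(get("protein"), get("term"), sc,
                   vocabulary = vocabulary, orientation = orientation,
                   zero_cap = zero_cap,
                   method = method %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Threshold predictions into per-protein annotation sets
#'
#' Keeps terms whose internal score is at least `tau_p` (inclusive). Proteins
#' left with no term are absent from the result: they are not annotatable at
#' this threshold.
#'
#' @param table an `fp_predictions`.
#' @param tau_p finite prediction-score threshold on the internal scale
#'   (`-Inf` keeps everything).
#' @return Named list protein -> non-empty character term set, class
#'   `fp_annotation_sets`, with attributes `tau_p`, `vocabulary`, `method`.
#' @export
threshold_annotations <- function(table, tau_p) {
  stopifnot(inherits(table, "fp_predictions"), length(tau_p) == 1L,
            !is.na(tau_p))
  keep <- table$score >= tau_p
  sets <- split(table$term[keep], table$protein[keep])
  structure(sets, class = "fp_annotation_sets", tau_p = tau_p,
            vocabulary = attr(table, "vocabulary"),
            method = attr(table, "method"))
}

#' Restrict a pair table to pairs annotatable by a method
#'
#' A pair is annotatable when both proteins carry at least one accepted term.
#' The returned table records the annotatable fraction of all pairs and,
#' when a `label` column is present, of sibling pairs.
#'
#' @param sets an `fp_annotation_sets` (or any named list of term sets).
#' @param pairs data.frame with columns `id1`, `id2` (and optionally `label`).
#' @return The annotatable subset of `pairs`, with attributes `frac_pairs`
#'   and `frac_siblings` (proportions in `[0,1]`, the latter `NA` without
#'   labels).
#' @export
annotatable_pairs <- function(sets, pairs) {
  stopifnot(is.data.frame(pairs), all(c("id1", "id2") %in% names(pairs)))
  ann <- names(sets)
  keep <- pairs$id1 %in% ann & pairs$id2 %in% ann
  out <- pairs[keep, , drop = FALSE]
  frac_sib <- NA_real_
  if ("label" %in% names(pairs) && any(pairs$label == "sibling")) {
    sib <- pairs$label == "sibling"
    frac_sib <- sum(keep & sib) / sum(sib)
  }
  structure(out,
            frac_pairs = if (nrow(pairs)) sum(keep) / nrow(pairs) else NA_real_,
            frac_siblings = frac_sib)
}
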