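#' Default bin schemes for pair characteristics
#'
#' Bin edges used in the enrichment analysis: sequence identity (percent)
#' `<40, 40-60, 60-80, 80-90`; TM score `0-0.5, 0.5-0.7, 0.7-1`; SNN score
#' `0-0.5, 0.5-0.98, 0.98-1`. Bins are left-closed/right-open with the last
#' bin right-closed.
#'
#' @param variable one of `"seq_identity"`, `"tm_score"`, `"snn_score"`.
#' @return list with `variable`, `edges` and human-readable `labels`.
#' @export
bin_scheme <- function(variable = c("seq_identity", "tm_score", "snn_score")) {
  variable <- match.arg(variable)
  edges <- switch(variable,
                  seq_identity = c(0, 40, 60, 80, 90),
                  tm_score = c(0, 0.5, 0.7, 1),
                  snn_score = c(0, 0.5, 0.98, 1))
  labels <- switch(variable,
                   seq_identity = c("<40%", "40%-60%", "60%-80%", "80%-90%"),
                   tm_score = c("0-0.5", "0.5-0.7", "0.7-1.0"),
                   snn_score = c("0-0.5", "0.5-0.98", "0.98-1.0"))
  list(variable = variable, edges = edges, labels = labels)
}

#' Bin pairs by a score or identity variable
#'
#' @param pairs data.frame carrying the binning variable as a column (`tm`,
#'   `snn` or `identity`).
#' @param scheme a [bin_scheme()] (or a list with `variable`, `edges`,
#'   `labels`).
#' @return Factor of bin labels, one per pair. Values outside the covered
#'   range are an error naming the offending pair.
#' @export
bin_pairs <- function(pairs, scheme) {
  col <- switch(scheme$variable,
                seq_identity = "identity", tm_score = "tm", snn_score = "snn")
  x <- pairs[[col]]
  if (is.null(x)) stop("pairs table lacks column '", col, "'")
  edges <- scheme$edges
  out_of_range <- x < edges[1L] | x > edges[length(edges)]
  if (any(out_of_range)) {
    i <- which(out_of_range)[1L]
    stop("value ", x[i], " outside bin range for pair ",
         pairs$id1[i], "-", pairs$id2[i])
  }
  # left-closed/right-open; last bin right-closed
  idx <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  idx <- pmin(idx, length(edges) - 1L)
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Fisher enrichment of predicted siblings in one bin
#'
#' Tests whether a method's predicted siblings over- or under-represent a bin
#' relative to the full pair universe, with the two-sided Fisher exact test
#' on the 2x2 table (predicted vs not) x (in bin vs not). The odds ratio is
#' the sample cross-product ratio, with Haldane 0.5 continuity correction
#' when any cell is zero.
#'
#' @param in_bin_predicted predicted siblings falling in the bin.
#' @param predicted_total all predicted siblings.
#' @param in_bin_universe universe pairs in the bin.
#' @param universe_total all universe pairs.
#' @return list: the four counts, `odds_ratio`, `p`, `direction` (`"+"`-style
#'   glyph placeholder filled by [enrichment_table()] after adjustment).
#' @export
fisher_enrichment <- function(in_bin_predicted, predicted_total,
                              in_bin_universe, universe_total) {
  if (in_bin_predicted > predicted_total || in_bin_universe > universe_total ||
      predicted_total > universe_total || in_bin_predicted > in_bin_universe) {
    stop("inconsistent counts: subset relations violated")
  }
  # rows: predicted / not-predicted; cols: in bin / not in bin
  a <- in_bin_predicted
  b <- predicted_total - in_bin_predicted
  c_ <- in_bin_universe - in_bin_predicted
  d <- (universe_total - in_bin_universe) - b
  if (d < 0) stop("inconsistent counts: subset relations violated")
  tab <- matrix(c(a, c_, b, d), 2L)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else (a * d) / (b * c_)
  list(in_bin_predicted = a, predicted_total = predicted_total,
       in_bin_universe = in_bin_universe, universe_total = universe_total,
       odds_ratio = or, p = min(p, 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] kept as the package's single
#' correction entry point (order-preserving, monotone, capped at 1).
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

# footnote-style significance glyph: +/- for p in [0.001, 0.05],
# ++/-- for p < 0.001
significance_glyph <- function(p, enriched) {
  ifelse(p < 0.001, ifelse(enriched, "++", "--"),
         ifelse(p <= 0.05, ifelse(enriched, "+", "-"), ""))
}

#' Per-bin enrichment table for one method
#'
#' Bins the pair universe by one variable, counts the method's predicted
#' siblings per bin, and tests each bin for enrichment/depletion. P-values
#' are BH-adjusted across the variable's bins (one family per method and
#' variable); significance glyphs use the adjusted values (raw values are
#' reported alongside): `+`/`-` for adjusted p in \[0.001, 0.05\], `++`/`--`
#' below 0.001.
#'
#' @param predicted data.frame `id1`, `id2`: the pairs the method calls
#'   siblings (must be a subset of `universe`).
#' @param universe data.frame of all pairs with the binning variable column.
#' @param scheme a [bin_scheme()].
#' @return data.frame: one row per bin with counts, odds ratio, raw and
#'   adjusted p, and the glyph.
#' @export
enrichment_table <- function(predicted, universe, scheme) {
  bins <- bin_pairs(universe, scheme)
  pred_key <- paste(predicted$id1, predicted$id2)
  uni_key <- paste(universe$id1, universe$id2)
  if (!all(pred_key %in% uni_key)) {
    stop("predicted pairs must be a subset of the universe")
  }
  is_pred <- uni_key %in% pred_key
  rows <- lapply(levels(bins), function(lv) {
    inb <- bins == lv
    fe <- fisher_enrichment(sum(inb & is_pred), sum(is_pred),
                            sum(inb), length(uni_key))
    data.frame(variable = scheme$variable, bin = lv,
               n_universe = sum(inb), n_predicted = sum(inb & is_pred),
               odds_ratio = fe$odds_ratio, p = fe$p)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- bh_adjust(out$p)
  out$glyph <- significance_glyph(out$p_bh, out$odds_ratio > 1)
  rownames(out) <- NULL
  out
}
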