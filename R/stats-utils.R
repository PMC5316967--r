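#' @title Shared elementary statistics
#' @name stats-utils
NULL

#' log2(x + 1) transform
#'
#' The analysis scale used throughout the pipeline for RSEM-like abundances.
#'
#' @param values Non-negative numeric vector or matrix.
#' @return Transformed values, same shape.
#' @export
log2_plus_one <- function(values) {
  if (any(values < 0, na.rm = TRUE))
    stop_validation("log2_plus_one requires non-negative input")
  log2(values + 1)
}

#' Normalize expression to a reference (housekeeping) gene
#'
#' Divides every gene's value in each sample by that sample's reference-gene
#' value. Samples where the reference is zero cannot be normalized; they are
#' dropped and listed in the `dropped_samples` attribute of the result.
#'
#' @param expr Gene x sample expression matrix.
#' @param reference_gene Gene symbol present in `expr`.
#' @return Normalized matrix over retained samples, with attribute
#'   `dropped_samples`.
#' @export
normalize_to_reference_gene <- function(expr, reference_gene) {
  if (!reference_gene %in% rownames(expr))
    stop_validation("reference gene not in expression matrix: ", reference_gene)
  ref <- expr[reference_gene, ]
  keep <- ref > 0
  if (!any(keep))
    stop_validation("all samples have zero reference-gene expression")
  out <- sweep(expr[, keep, drop = FALSE], 2, ref[keep], "/")
  attr(out, "dropped_samples") <- colnames(expr)[!keep]
  out
}

complete_pairs <- function(x, y) {
  if (length(x) != length(y)) stop_validation("vectors must have equal length")
  ok <- is.finite(x) & is.finite(y)
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Pearson correlation with pairwise-complete observations
#'
#' Returns `NA` (the undefined-correlation signal) when either vector is
#' constant after pairwise removal of missing entries; errors when fewer than
#' 3 complete pairs remain.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
pearson_correlation <- function(x, y) {
  p <- complete_pairs(x, y)
  if (p$n < 3L) stop_validation("need at least 3 complete pairs, got ", p$n)
  if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0) return(NA_real_)
  stats::cor(p$x, p$y)
}

#' Spearman rank correlation (average ranks for ties)
#'
#' @inheritParams pearson_correlation
#' @return Rank correlation in `[-1, 1]`, or `NA_real_` if undefined.
#' @export
spearman_correlation <- function(x, y) {
  p <- complete_pairs(x, y)
  if (p$n < 3L) stop_validation("need at least 3 complete pairs, got ", p$n)
  rx <- rank(p$x); ry <- rank(p$y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# Correlate each row of a log-scale matrix with one vector; NA for rows
# constant on the complete pairs. Used by the network and profile stages.
row_correlations <- function(mat, v, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  apply(mat, 1L, function(row) {
    p <- complete_pairs(row, v)
    if (p$n < 3L) return(NA_real_)
    if (method == "spearman") { p$x <- rank(p$x); p$y <- rank(p$y) }
    if (stats::sd(p$x) == 0 || stats::sd(p$y) == 0) return(NA_real_)
    stats::cor(p$x, p$y)
  })
}

# Deterministic fan-out of one user seed into per-stage sub-seeds, kept
# inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  base <- as.numeric(seed) %% 2147483647
  key <- if (is.character(stage)) sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
         else as.numeric(stage)
  as.integer((base * 7919 + key * 104729 + 17) %% 2147483629)
}
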