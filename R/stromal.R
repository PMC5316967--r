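#' @title Single-sample stromal signature scoring
#' @description ESTIMATE-style stromal content is proxied by a single-sample
#'   rank-weighted enrichment (ssGSEA) of a stromal gene signature; scores
#'   are then associated with individual genes by Spearman correlation.
#'   Externally computed score tables can be substituted for exact
#'   replication of published scores.
#' @name stromal-scoring
NULL

#' Single-sample gene-set enrichment (ssGSEA) score
#'
#' Genes are ranked by expression within the sample (ascending rank
#' `v in 1..N`, average ranks for ties). Walking down the descending-rank
#' order, the score accumulates the gap between the weighted in-set
#' cumulative distribution (weights `v^alpha`, normalized by the in-set
#' total) and the uniform out-of-set cumulative distribution:
#' `score = sum_k [P_in(k) - P_out(k)]`.
#'
#' @param sample_expression Named numeric vector (one sample's expression).
#' @param gene_set Character vector of gene symbols; must overlap the names
#'   of `sample_expression`.
#' @param alpha Rank-weight exponent, `>= 0` (default 0.25).
#' @return Single numeric enrichment score; 0 by convention when the set
#'   covers all genes.
#' @export
ssgsea_score <- function(sample_expression, gene_set, alpha = 0.25) {
  if (alpha < 0) stop_validation("alpha must be >= 0")
  genes <- names(sample_expression)
  if (is.null(genes)) stop_validation("sample_expression must be named by gene")
  inset <- genes %in% gene_set
  m <- sum(inset); N <- length(genes)
  if (m == 0L) stop_validation("gene set does not overlap the expression rows")
  if (m == N) return(0)
  v <- rank(sample_expression, ties.method = "average")
  ord <- order(v, decreasing = TRUE)
  inset <- inset[ord]
  w <- v[ord]^alpha
  w[!inset] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset) / (N - m)
  sum(p_in - p_out)
}

#' Stromal scores for all primary-tumour samples
#'
#' [ssgsea_score()] of the stromal signature on each tumour sample's
#' log2(expression + 1) values.
#'
#' @param bundle A `cohort_bundle`.
#' @param stromal_signature Character vector of signature genes, or a
#'   `gene_set_collection` plus `set_name`.
#' @param set_name Set to use when a collection is given.
#' @param alpha Rank-weight exponent (default 0.25).
#' @return Data frame with `sample_id` and `stromal_score`.
#' @export
stromal_scores <- function(bundle, stromal_signature, set_name = NULL,
                           alpha = 0.25) {
  if (inherits(stromal_signature, "gene_set_collection")) {
    if (is.null(set_name) || !set_name %in% names(stromal_signature$sets))
      stop_validation("set_name must name a set in the collection")
    stromal_signature <- stromal_signature$sets[[set_name]]
  }
  tum <- samples_of(bundle, "primary")
  le <- log2_plus_one(bundle$expression[, tum, drop = FALSE])
  scores <- vapply(tum, function(s) ssgsea_score(le[, s], stromal_signature,
                                                 alpha = alpha), 0)
  data.frame(sample_id = tum, stromal_score = unname(scores),
             stringsAsFactors = FALSE)
}

#' Association of one gene with stromal scores
#'
#' Spearman correlation of the gene's log2(expression + 1) with the stromal
#' score across the scored tumour samples.
#'
#' @param bundle A `cohort_bundle`.
#' @param gene Gene symbol.
#' @param scores Score table from [stromal_scores()] (or an external table
#'   with the same columns).
#' @return Spearman rho, or `NA` when undefined (constant expression).
#' @export
stromal_association <- function(bundle, gene, scores) {
  if (!gene %in% rownames(bundle$expression))
    stop_validation("gene not in expression matrix: ", gene)
  common <- intersect(scores$sample_id, colnames(bundle$expression))
  if (length(common) < 3L) stop_validation("scores must cover >= 3 samples")
  expr <- log2_plus_one(bundle$expression[gene, common])
  sc <- scores$stromal_score[match(common, scores$sample_id)]
  spearman_correlation(expr, sc)
}
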