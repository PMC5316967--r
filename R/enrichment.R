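#' @title Per-sample gene-set enrichment versus a mean reference
#' @description GAGE-style one-on-one enrichment: each tumour sample is
#'   compared against a formulated reference sample of per-gene mean
#'   expression; the set statistic is a two-sample t of in-set versus
#'   background fold changes. Set statistics are then Spearman-correlated
#'   with seed-gene expression across samples.
#' @name enrichment-correlation
NULL

#' Mean reference sample
#'
#' Per-gene arithmetic mean of log2-scale expression across the columns of
#' the supplied matrix (at least 2 samples).
#'
#' @param log_expr Gene x sample matrix already on the log2(x + 1) scale.
#' @return Named numeric vector, one mean per gene.
#' @export
mean_reference_sample <- function(log_expr) {
  if (is.null(dim(log_expr)) || ncol(log_expr) < 2L)
    stop_validation("need at least 2 samples to form a reference")
  rowMeans(log_expr)
}

#' Per-sample gene-set statistic against a reference
#'
#' Fold changes `fc_g = sample_g - reference_g` (log2 scale); the statistic
#' is `(mean_set(fc) - mean_bg(fc)) / sqrt(s_set^2/m + s_bg^2/(N-m))` with
#' the background being all measured genes outside the set.
#'
#' @param sample_log_expr Named numeric vector (one sample, log2 scale).
#' @param reference Named numeric vector from [mean_reference_sample()].
#' @param gene_set Character vector of set genes (>= 2 measured; at least 2
#'   background genes must remain).
#' @return t-like statistic, or `NA` when both variances are zero.
#' @export
gage_set_statistic <- function(sample_log_expr, reference, gene_set) {
  genes <- names(sample_log_expr)
  if (is.null(genes) || !identical(genes, names(reference)))
    stop_validation("sample and reference must share identical gene names")
  inset <- genes %in% gene_set
  m <- sum(inset); N <- length(genes)
  if (m < 2L) stop_validation("gene set must have >= 2 measured genes")
  if (N - m < 2L) stop_validation("background must have >= 2 genes")
  fc <- sample_log_expr - reference
  v_in <- stats::var(fc[inset]); v_out <- stats::var(fc[!inset])
  denom <- sqrt(v_in / m + v_out / (N - m))
  num <- mean(fc[inset]) - mean(fc[!inset])
  # identical-to-reference (all fc constant): no enrichment, exactly 0;
  # zero variances with unequal means stay undefined
  if (denom == 0) return(if (num == 0) 0 else NA_real_)
  num / denom
}

#' Gene-set x sample enrichment matrix for one cohort
#'
#' Builds the per-sample statistic of every set (with at least
#' `min_set_size` measured genes) for every primary-tumour sample, against
#' the cohort's mean reference sample.
#'
#' @param bundle A `cohort_bundle`.
#' @param gene_sets A `gene_set_collection` or named list of gene vectors.
#' @param min_set_size Minimum measured genes per set (default 2).
#' @return Matrix, set names x sample ids; attribute `dropped_sets` lists
#'   sets below the size floor.
#' @export
enrichment_matrix <- function(bundle, gene_sets, min_set_size = 2L) {
  sets <- if (inherits(gene_sets, "gene_set_collection")) gene_sets$sets else gene_sets
  tum <- samples_of(bundle, "primary")
  if (length(tum) < 2L) stop_validation("need at least 2 tumour samples")
  le <- log2_plus_one(bundle$expression[, tum, drop = FALSE])
  ref <- mean_reference_sample(le)
  measured <- lapply(sets, function(s) intersect(s, rownames(le)))
  keep <- vapply(measured, length, 0L) >= min_set_size &
    nrow(le) - vapply(measured, length, 0L) >= 2L
  out <- matrix(NA_real_, nrow = sum(keep), ncol = length(tum),
                dimnames = list(names(sets)[keep], tum))
  fc <- le - ref  # recycled column-wise
  for (nm in rownames(out)) {
    inset <- rownames(le) %in% measured[[nm]]
    m <- sum(inset); N <- nrow(le)
    mu_in <- colMeans(fc[inset, , drop = FALSE])
    mu_out <- colMeans(fc[!inset, , drop = FALSE])
    v_in <- apply(fc[inset, , drop = FALSE], 2, stats::var)
    v_out <- apply(fc[!inset, , drop = FALSE], 2, stats::var)
    denom <- sqrt(v_in / m + v_out / (N - m))
    stat <- (mu_in - mu_out) / denom
    stat[denom == 0 & mu_in == mu_out] <- 0
    stat[denom == 0 & mu_in != mu_out] <- NA_real_
    out[nm, ] <- stat
  }
  attr(out, "dropped_sets") <- names(sets)[!keep]
  out
}

#' Correlation of set enrichments with a seed gene
#'
#' Spearman-correlates each set's per-sample statistic vector with the seed
#' gene's log2(expression + 1) over the same tumour samples. A set is
#' retained when `|rho|` strictly exceeds `threshold`.
#'
#' @param bundle A `cohort_bundle`.
#' @param gene_sets Gene sets, as for [enrichment_matrix()].
#' @param seed_gene Seed gene symbol.
#' @param threshold Retention threshold on `|rho|` (default 0.5, strict).
#' @param min_set_size Passed to [enrichment_matrix()].
#' @return Data frame with `set`, `rho`, `n`, `retained`.
#' @export
enrichment_correlation_profile <- function(bundle, gene_sets, seed_gene,
                                           threshold = 0.5, min_set_size = 2L) {
  if (!seed_gene %in% rownames(bundle$expression))
    stop_validation("seed gene not in expression matrix: ", seed_gene)
  em <- enrichment_matrix(bundle, gene_sets, min_set_size = min_set_size)
  seed <- log2_plus_one(bundle$expression[seed_gene, colnames(em)])
  rho <- row_correlations(em, seed, method = "spearman")
  n <- rowSums(is.finite(em))
  out <- data.frame(set = rownames(em), rho = unname(rho), n = unname(n),
                    retained = !is.na(rho) & abs(rho) > threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
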