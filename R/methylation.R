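#' @title CpG methylation-expression analysis
#' @name methylation-analysis
NULL

meth_samples <- function(bundle) {
  if (is.null(bundle$methylation))
    stop_validation("cohort ", bundle$cancer_code, " has no methylation data")
  intersect(colnames(bundle$methylation$beta), colnames(bundle$expression))
}

#' Per-probe methylation-expression correlation profile
#'
#' For every CpG probe assigned to the gene's locus, correlates beta values
#' with the gene's log2(expression + 1) across all tissue groups pooled
#' (normal, primary, metastatic), or within one group via `group`. Probes
#' with fewer than 3 complete pairs, or constant on them, get an undefined
#' (`NA`) correlation.
#'
#' @param bundle A `cohort_bundle` with methylation data.
#' @param gene Gene symbol present in the expression matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param group Optional tissue group to restrict to.
#' @return Data frame with `probe_id`, `position`, `r`, `n_pairs`.
#' @export
probe_expression_correlations <- function(bundle, gene,
                                          method = c("pearson", "spearman"),
                                          group = NULL) {
  method <- match.arg(method)
  samples <- meth_samples(bundle)
  if (!is.null(group)) samples <- intersect(samples, samples_of(bundle, group))
  if (!gene %in% rownames(bundle$expression))
    stop_validation("gene not in expression matrix: ", gene)
  info <- bundle$methylation$probe_info
  sel <- info$gene == gene
  if (!any(sel)) stop_validation("no probes assigned to gene ", gene)
  expr <- log2_plus_one(bundle$expression[gene, samples])
  beta <- bundle$methylation$beta[info$probe_id[sel], samples, drop = FALSE]
  res <- lapply(seq_len(nrow(beta)), function(i) {
    b <- beta[i, ]
    ok <- is.finite(b) & is.finite(expr)
    n <- sum(ok)
    r <- if (n < 3L) NA_real_
         else tryCatch(if (method == "pearson") pearson_correlation(b[ok], expr[ok])
                       else spearman_correlation(b[ok], expr[ok]),
                       error = function(e) NA_real_)
    data.frame(probe_id = rownames(beta)[i],
               position = info$position[sel][i], r = r, n_pairs = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Locus-level methylation profile of one tissue group
#'
#' Per-probe arithmetic mean beta and standard error of the mean within the
#' group, ordered by genomic position.
#'
#' @param bundle A `cohort_bundle` with methylation data.
#' @param gene Gene whose locus probes are profiled.
#' @param group Tissue group (`"normal"`, `"primary"`, `"metastatic"`).
#' @return Data frame with `probe_id`, `position`, `mean_beta`, `sem`, `n`.
#' @export
locus_profile <- function(bundle, gene, group) {
  group <- match.arg(group, TISSUE_TYPES)
  samples <- intersect(meth_samples(bundle), samples_of(bundle, group))
  if (length(samples) < 2L)
    stop_validation("need at least 2 samples in group ", group)
  info <- bundle$methylation$probe_info
  sel <- info$gene == gene
  if (!any(sel)) stop_validation("no probes assigned to gene ", gene)
  beta <- bundle$methylation$beta[info$probe_id[sel], samples, drop = FALSE]
  n <- rowSums(is.finite(beta))
  means <- rowMeans(beta, na.rm = TRUE)
  sds <- apply(beta, 1, stats::sd, na.rm = TRUE)
  out <- data.frame(probe_id = rownames(beta), position = info$position[sel],
                    mean_beta = means, sem = sds / sqrt(pmax(n, 1)), n = n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

#' Matched-patient expression and methylation view
#'
#' For each patient triplet (normal, primary, metastatic sample ids),
#' tabulates the gene's expression and the per-probe beta values at its
#' locus for each tissue. Triplets referencing unknown samples produce
#' flagged rows.
#'
#' @param bundle A `cohort_bundle` with methylation data.
#' @param gene Gene of interest.
#' @param patient_triplets Data frame with columns `patient_id`, `normal`,
#'   `primary`, `metastatic` (sample ids, `NA` allowed).
#' @return Long data frame: one row per patient x tissue x probe, with
#'   `expression`, `beta` and a `flagged` column.
#' @export
paired_patient_view <- function(bundle, gene, patient_triplets) {
  need <- c("patient_id", "normal", "primary", "metastatic")
  miss <- setdiff(need, names(patient_triplets))
  if (length(miss)) stop_format("triplet table missing column(s): ",
                                paste(miss, collapse = ", "))
  info <- bundle$methylation$probe_info
  sel <- info$gene == gene
  if (!any(sel)) stop_validation("no probes assigned to gene ", gene)
  probes <- info$probe_id[sel]
  positions <- info$position[sel]
  rows <- list()
  for (i in seq_len(nrow(patient_triplets))) {
    pt <- patient_triplets[i, ]
    for (tissue in c("normal", "primary", "metastatic")) {
      sid <- pt[[tissue]]
      known <- !is.na(sid) && sid %in% colnames(bundle$expression) &&
        sid %in% colnames(bundle$methylation$beta)
      expr <- if (known) bundle$expression[gene, sid] else NA_real_
      beta <- if (known) bundle$methylation$beta[probes, sid] else
        rep(NA_real_, length(probes))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pt$patient_id, tissue_type = tissue,
        sample_id = if (is.na(sid)) NA_character_ else as.character(sid),
        flagged = !known, expression = expr,
        probe_id = probes, position = positions, beta = unname(beta),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
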