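#' @title Cohort data model
#' @description Validated containers for one cancer cohort: a gene x sample
#'   expression matrix on the RSEM-normalized (non-negative, right-skewed)
#'   scale, sample tissue annotations, an overall-survival clinical table and
#'   an optional CpG methylation beta matrix with probe coordinates.
#' @name cohort-model
NULL

TISSUE_TYPES <- c("normal", "primary", "metastatic")

stop_validation <- function(...) {
  stop(structure(class = c("stromascreen_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_format <- function(...) {
  stop(structure(class = c("stromascreen_format_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Validate a gene x sample expression matrix
#'
#' Checks the invariants of the expression container: a numeric matrix with
#' unique gene row names and unique sample column names, all values finite and
#' non-negative.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   `dimnames` giving gene symbols and sample identifiers.
#' @return The validated matrix, invisibly usable as-is.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_validation("expression must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_validation("expression matrix must have at least one gene and one sample")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop_validation("expression matrix needs gene row names and sample column names")
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g))
    stop_validation("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s))
    stop_validation("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop_validation("expression values must be finite and non-missing")
  if (any(values < 0))
    stop_validation("expression values must be non-negative")
  values
}

#' Validate a sample annotation table
#'
#' @param annotations Data frame with columns `sample_id`, `cancer_code` and
#'   `tissue_type` (one of `"normal"`, `"primary"`, `"metastatic"`).
#' @return The validated data frame.
#' @export
validate_annotations <- function(annotations) {
  need <- c("sample_id", "cancer_code", "tissue_type")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop_format("annotation table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotations$sample_id))
    stop_validation("duplicate sample_id in annotations: ",
                    paste(unique(annotations$sample_id[duplicated(annotations$sample_id)]),
                          collapse = ", "))
  bad <- setdiff(unique(annotations$tissue_type), TISSUE_TYPES)
  if (length(bad))
    stop_validation("tissue_type must be one of ", paste(TISSUE_TYPES, collapse = "/"),
                    "; found: ", paste(bad, collapse = ", "))
  annotations[, need]
}

#' Validate an overall-survival clinical table
#'
#' @param clinical Data frame with columns `sample_id`, `os_time` (days,
#'   strictly positive) and `os_event` (1 = death observed, 0 = censored).
#' @return The validated data frame.
#' @export
validate_clinical <- function(clinical) {
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop_format("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(clinical$sample_id))
    stop_validation("duplicate sample_id in clinical table")
  if (anyNA(clinical$os_time) || any(!is.finite(clinical$os_time)) || any(clinical$os_time <= 0))
    stop_validation("os_time must be strictly positive and finite")
  if (!all(clinical$os_event %in% c(0, 1)))
    stop_validation("os_event must be 0 or 1")
  clinical <- clinical[, need]
  clinical$os_time <- as.numeric(clinical$os_time)
  clinical$os_event <- as.integer(clinical$os_event)
  clinical
}

#' Construct a validated methylation matrix
#'
#' Bundles a probe x sample beta-value matrix with probe coordinates and
#' probe-to-gene assignment. Beta values are methylation fractions in
#' `[0, 1]`; missing values are allowed (450k-style matrices contain them).
#'
#' @param beta Numeric probe x sample matrix with probe row names and sample
#'   column names; values in `[0, 1]` or `NA`.
#' @param probe_info Data frame with columns `probe_id`, `position` (1-based
#'   integer coordinate on the locus axis) and `gene` (assigned gene symbol),
#'   one row per row of `beta`, in the same order.
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(beta, probe_info) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop_validation("beta must be a numeric matrix")
  need <- c("probe_id", "position", "gene")
  miss <- setdiff(need, names(probe_info))
  if (length(miss))
    stop_format("probe info missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(probe_info) != nrow(beta))
    stop_validation("probe info rows must match beta rows")
  if (anyDuplicated(probe_info$probe_id))
    stop_validation("duplicate probe_id")
  if (is.null(rownames(beta))) rownames(beta) <- probe_info$probe_id
  if (!identical(rownames(beta), as.character(probe_info$probe_id)))
    stop_validation("beta row names must equal probe_id, in order")
  if (any(!is.finite(probe_info$position)))
    stop_validation("probe positions must be finite")
  finite <- beta[!is.na(beta)]
  if (any(finite < 0 | finite > 1))
    stop_validation("beta values must lie in [0, 1] (or be missing)")
  ord <- order(probe_info$position)
  structure(list(beta = beta[ord, , drop = FALSE],
                 probe_info = probe_info[ord, need, drop = FALSE]),
            class = "methylation_matrix")
}

#' Assemble one cancer cohort
#'
#' Builds a validated `cohort_bundle` from its parts and enforces the
#' cross-table invariants: every expression sample is annotated exactly once,
#' clinical and methylation samples are subsets of expression samples.
#'
#' @param cancer_code Short cohort label (e.g. a TCGA-style code).
#' @param expression Gene x sample matrix, see [validate_expression_matrix()].
#' @param annotations Sample annotation data frame, see [validate_annotations()].
#' @param clinical Clinical table, see [validate_clinical()].
#' @param methylation Optional [methylation_matrix()].
#' @return Object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(cancer_code, expression, annotations, clinical,
                          methylation = NULL) {
  expression <- validate_expression_matrix(expression)
  annotations <- validate_annotations(annotations)
  clinical <- validate_clinical(clinical)
  samples <- colnames(expression)
  if (!setequal(annotations$sample_id, samples))
    stop_validation("annotations must cover exactly the expression samples")
  extra <- setdiff(clinical$sample_id, samples)
  if (length(extra))
    stop_validation("clinical sample(s) absent from expression: ",
                    paste(utils::head(extra, 5), collapse = ", "))
  if (!is.null(methylation)) {
    if (!inherits(methylation, "methylation_matrix"))
      stop_validation("methylation must be a methylation_matrix")
    extra_m <- setdiff(colnames(methylation$beta), samples)
    if (length(extra_m))
      stop_validation("methylation sample(s) absent from expression: ",
                      paste(utils::head(extra_m, 5), collapse = ", "))
  }
  structure(list(cancer_code = as.character(cancer_code)[1],
                 expression = expression,
                 annotations = annotations,
                 clinical = clinical,
                 methylation = methylation),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle> ", x$cancer_code, ": ",
      nrow(x$expression), " genes x ", ncol(x$expression), " samples (",
      sum(x$annotations$tissue_type == "primary"), " primary, ",
      sum(x$annotations$tissue_type == "normal"), " normal, ",
      sum(x$annotations$tissue_type == "metastatic"), " metastatic); ",
      nrow(x$clinical), " clinical rows; methylation: ",
      if (is.null(x$methylation)) "none" else
        paste0(nrow(x$methylation$beta), " probes"), "\n", sep = "")
  invisible(x)
}

#' Sample identifiers of a tissue group
#'
#' @param bundle A `cohort_bundle`.
#' @param tissue One of `"normal"`, `"primary"`, `"metastatic"`.
#' @return Character vector of sample identifiers, in expression column order.
#' @export
samples_of <- function(bundle, tissue) {
  tissue <- match.arg(tissue, TISSUE_TYPES)
  ids <- bundle$annotations$sample_id[bundle$annotations$tissue_type == tissue]
  intersect(colnames(bundle$expression), ids)
}
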