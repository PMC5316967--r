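#' @title Cohort and gene-set file I/O
#' @description TSV readers/writers for the cohort dialects and a GMT parser.
#'   Numeric values round-trip bit-for-bit (written with 17 significant
#'   digits), so `read_cohort(write_cohort(b))` reproduces `b` exactly.
#' @name cohort-io
NULL

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_format(what, " file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_format(what, " file ", basename(path), " missing column(s): ",
                paste(miss, collapse = ", "))
  df
}

#' Read one cohort from TSV files
#'
#' Expression TSV: first column `gene`, remaining columns samples.
#' Annotation TSV: `sample_id`, `cancer_code`, `tissue_type`.
#' Clinical TSV: `sample_id`, `os_time`, `os_event`.
#' Methylation TSV (optional): `probe_id`, `position`, `gene`, then samples.
#'
#' @param expression_path,annotation_path,clinical_path,methylation_path File
#'   paths; `methylation_path` may be `NULL`.
#' @return A validated [cohort_bundle()].
#' @export
read_cohort <- function(expression_path, annotation_path, clinical_path,
                        methylation_path = NULL) {
  ex <- read_tsv_checked(expression_path, "gene", "expression")
  if (ncol(ex) < 2L) stop_format("expression file has no sample columns")
  genes <- as.character(ex$gene)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop_validation("duplicated gene symbol(s) in expression file: ",
                    paste(dup, collapse = ", "))
  values <- as.matrix(ex[, setdiff(names(ex), "gene"), drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes

  ann <- read_tsv_checked(annotation_path, c("sample_id", "cancer_code", "tissue_type"),
                          "annotation")
  cl <- read_tsv_checked(clinical_path, c("sample_id", "os_time", "os_event"),
                         "clinical")
  meth <- NULL
  if (!is.null(methylation_path)) {
    mm <- read_tsv_checked(methylation_path, c("probe_id", "position", "gene"),
                           "methylation")
    scols <- setdiff(names(mm), c("probe_id", "position", "gene"))
    if (!length(scols)) stop_format("methylation file has no sample columns")
    beta <- as.matrix(mm[, scols, drop = FALSE])
    storage.mode(beta) <- "double"
    rownames(beta) <- as.character(mm$probe_id)
    meth <- methylation_matrix(beta, data.frame(probe_id = as.character(mm$probe_id),
                                                position = mm$position,
                                                gene = as.character(mm$gene),
                                                stringsAsFactors = FALSE))
  }
  code <- unique(ann$cancer_code)
  if (length(code) != 1L)
    stop_validation("annotation file must contain a single cancer_code; found: ",
                    paste(code, collapse = ", "))
  cohort_bundle(code, values, ann, cl, meth)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_numeric_tsv <- function(df, num_cols, path) {
  out <- df
  for (cc in intersect(num_cols, names(out))) out[[cc]] <- fmt_num(out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a cohort to a directory of TSV files
#'
#' Emits `expression.tsv`, `annotations.tsv`, `clinical.tsv` and, when
#' present, `methylation.tsv` in the dialects read by [read_cohort()].
#'
#' @param bundle A valid `cohort_bundle`.
#' @param directory Output directory (created if needed).
#' @return Named character vector of written file paths.
#' @export
write_cohort <- function(bundle, directory) {
  if (!inherits(bundle, "cohort_bundle")) stop_validation("not a cohort_bundle")
  if (nrow(bundle$expression) == 0L || ncol(bundle$expression) == 0L)
    stop_validation("refusing to write an empty expression matrix")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)

  paths <- c(expression = file.path(directory, "expression.tsv"),
             annotations = file.path(directory, "annotations.tsv"),
             clinical = file.path(directory, "clinical.tsv"))
  ex <- data.frame(gene = rownames(bundle$expression),
                   apply(bundle$expression, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(ex, paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$annotations, paths[["annotations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_numeric_tsv(bundle$clinical, c("os_time", "os_event"), paths[["clinical"]])
  if (!is.null(bundle$methylation)) {
    m <- bundle$methylation
    bchr <- apply(m$beta, 2, function(col) ifelse(is.na(col), "NA", fmt_num(col)))
    if (is.null(dim(bchr))) bchr <- matrix(bchr, nrow = nrow(m$beta),
                                           dimnames = dimnames(m$beta))
    md <- data.frame(probe_id = m$probe_info$probe_id,
                     position = m$probe_info$position,
                     gene = m$probe_info$gene,
                     bchr, check.names = FALSE, stringsAsFactors = FALSE)
    mp <- file.path(directory, "methylation.tsv")
    utils::write.table(md, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, methylation = mp)
  }
  paths
}

#' Read a directory of cohorts
#'
#' Each subdirectory of `dir` holding an `expression.tsv` is read as one
#' cohort via [read_cohort()].
#'
#' @param dir Parent directory.
#' @return Named list of `cohort_bundle`s, keyed by cancer code.
#' @export
read_cohort_dir <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "expression.tsv"))]
  if (!length(subs)) stop_format("no cohort subdirectories under ", dir)
  bundles <- lapply(subs, function(d) {
    mp <- file.path(d, "methylation.tsv")
    read_cohort(file.path(d, "expression.tsv"),
                file.path(d, "annotations.tsv"),
                file.path(d, "clinical.tsv"),
                if (file.exists(mp)) mp else NULL)
  })
  names(bundles) <- vapply(bundles, function(b) b$cancer_code, "")
  bundles
}

#' Parse a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then one or more gene
#' symbols per line. Duplicate symbols within a set are collapsed (first
#' occurrence kept).
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop_format("GMT line ", i, " has fewer than 3 fields")
    nm <- fields[1]
    if (nm %in% names(sets)) stop_format("duplicate gene-set name: ", nm)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_format("GMT line ", i, " has no gene symbols")
    sets[[nm]] <- genes
    desc[nm] <- fields[2]
  }
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection` or named list of gene vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets else collection
  desc <- if (inherits(collection, "gene_set_collection")) collection$descriptions
          else stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
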