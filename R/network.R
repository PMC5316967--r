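#' @title Multi-cancer consensus co-expression network
#' @description Genes correlated with both seed genes (Pearson r above a
#'   threshold on log2(expr + 1)) in at least a required fraction of each
#'   seed's cancer list form the consensus set; edges are drawn between
#'   node pairs whose correlation in one designated cohort exceeds the edge
#'   threshold.
#' @name consensus-network
NULL

#' Genome-wide correlation profile of one seed gene in one cohort
#'
#' Pearson r of every gene's log2(expression + 1) with the seed gene across
#' primary-tumour samples; constant genes get an undefined (`NA`) entry and
#' the seed gene's own entry is 1.
#'
#' @param bundle A `cohort_bundle` with >= 3 tumour samples.
#' @param seed_gene Seed gene symbol.
#' @param genes Optional subset of genes to profile (default all).
#' @return Data frame with `gene` and `r`; attributes `cancer_code` and
#'   `seed_gene`.
#' @export
seedgene_correlation_profile <- function(bundle, seed_gene, genes = NULL) {
  if (!seed_gene %in% rownames(bundle$expression))
    stop_validation("seed gene not in expression matrix: ", seed_gene)
  tum <- samples_of(bundle, "primary")
  if (length(tum) < 3L) stop_validation("need >= 3 tumour samples")
  if (is.null(genes)) genes <- rownames(bundle$expression)
  le <- log2_plus_one(bundle$expression[genes, tum, drop = FALSE])
  seed <- log2_plus_one(bundle$expression[seed_gene, tum])
  r <- row_correlations(le, seed, method = "pearson")
  if (seed_gene %in% genes && !is.na(stats::sd(seed)) && stats::sd(seed) > 0)
    r[seed_gene] <- 1
  out <- data.frame(gene = genes, r = unname(r), stringsAsFactors = FALSE)
  attr(out, "cancer_code") <- bundle$cancer_code
  attr(out, "seed_gene") <- seed_gene
  out
}

profile_r_matrix <- function(profiles) {
  genes <- sort(unique(unlist(lapply(profiles, `[[`, "gene"))))
  mat <- vapply(profiles, function(p) p$r[match(genes, p$gene)],
                numeric(length(genes)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(genes))
  rownames(mat) <- genes
  mat
}

#' Consensus gene set across two seed genes' cancer lists
#'
#' A gene is included iff its correlation with seed A exceeds `r_threshold`
#' (strictly) in at least `frac_threshold` (inclusive) of the cancers in
#' list A, and the same holds for seed B over list B. Undefined correlations
#' count as not passing. The seed genes themselves are excluded from the
#' returned list (they are added back as marked nodes by
#' [build_network()]).
#'
#' @param profiles_a,profiles_b Lists of [seedgene_correlation_profile()]
#'   outputs over each seed's cancer list (non-empty).
#' @param r_threshold Correlation threshold (default 0.5, strict).
#' @param frac_threshold Required fraction of cancers (default 0.5,
#'   inclusive).
#' @return Sorted character vector of consensus genes.
#' @export
consensus_gene_set <- function(profiles_a, profiles_b, r_threshold = 0.5,
                               frac_threshold = 0.5) {
  if (!length(profiles_a) || !length(profiles_b))
    stop_validation("both cancer lists must be non-empty")
  pass_frac <- function(profiles) {
    mat <- profile_r_matrix(profiles)
    hits <- rowSums(!is.na(mat) & mat > r_threshold)
    hits / length(profiles)
  }
  fa <- pass_frac(profiles_a)
  fb <- pass_frac(profiles_b)
  genes <- intersect(names(fa)[fa >= frac_threshold],
                     names(fb)[fb >= frac_threshold])
  seeds <- unique(c(vapply(profiles_a, attr, "", "seed_gene"),
                    vapply(profiles_b, attr, "", "seed_gene")))
  sort(setdiff(genes, seeds))
}

#' Build the consensus co-expression network in a designated cohort
#'
#' Nodes are the consensus genes plus the seed genes (marked); an undirected
#' edge joins two nodes when the Pearson correlation of their
#' log2(expression + 1) across the designated cohort's primary tumours
#' strictly exceeds `edge_threshold`. Genes absent from the designated
#' cohort stay as edgeless nodes and are recorded.
#'
#' @param designated_bundle The cohort supplying edge weights (>= 3 tumour
#'   samples).
#' @param gene_list Consensus genes from [consensus_gene_set()].
#' @param seed_genes Seed gene symbols to mark.
#' @param edge_threshold Strict edge threshold on r (default 0.8).
#' @return Object of class `consensus_network`: list with `nodes` (data
#'   frame `gene`, `is_seed`), `edges` (data frame `gene_a`, `gene_b`,
#'   `weight`), `edge_threshold`, `cancer_code`, `missing_genes`.
#' @export
build_network <- function(designated_bundle, gene_list, seed_genes,
                          edge_threshold = 0.8) {
  tum <- samples_of(designated_bundle, "primary")
  if (length(tum) < 3L) stop_validation("designated cohort needs >= 3 tumour samples")
  nodes <- unique(c(gene_list, seed_genes))
  present <- intersect(nodes, rownames(designated_bundle$expression))
  missing <- setdiff(nodes, present)
  edges <- data.frame(gene_a = character(), gene_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(present) >= 2L) {
    le <- t(log2_plus_one(designated_bundle$expression[present, tum, drop = FALSE]))
    cm <- suppressWarnings(stats::cor(le, use = "pairwise.complete.obs"))
    idx <- which(upper.tri(cm) & !is.na(cm) & cm > edge_threshold, arr.ind = TRUE)
    if (nrow(idx)) {
      ga <- rownames(cm)[idx[, 1]]; gb <- colnames(cm)[idx[, 2]]
      swap <- ga > gb
      edges <- data.frame(gene_a = ifelse(swap, gb, ga),
                          gene_b = ifelse(swap, ga, gb),
                          weight = cm[idx], stringsAsFactors = FALSE)
      edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = data.frame(gene = sort(nodes),
                                    is_seed = sort(nodes) %in% seed_genes,
                                    stringsAsFactors = FALSE),
                 edges = edges, edge_threshold = edge_threshold,
                 cancer_code = designated_bundle$cancer_code,
                 missing_genes = missing),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat("<consensus_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$is_seed), " seeds), ", nrow(x$edges),
      " edges with r > ", x$edge_threshold, " in ", x$cancer_code, "\n", sep = "")
  invisible(x)
}

#' Per-cohort pairwise gene-gene correlation matrix
#'
#' Symmetric Pearson correlation matrix of log2(expression + 1) over the
#' cohort's primary tumours, for a gene panel.
#'
#' @param bundle A `cohort_bundle`.
#' @param genes At least 2 genes present in the cohort.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation_matrix <- function(bundle, genes) {
  genes <- intersect(genes, rownames(bundle$expression))
  if (length(genes) < 2L) stop_validation("need >= 2 genes present in the cohort")
  tum <- samples_of(bundle, "primary")
  if (length(tum) < 3L) stop_validation("need >= 3 tumour samples")
  le <- t(log2_plus_one(bundle$expression[genes, tum, drop = FALSE]))
  cm <- suppressWarnings(stats::cor(le, use = "pairwise.complete.obs"))
  diag(cm) <- 1
  cm
}

#' Elementwise average of per-cancer correlation matrices
#'
#' @param matrices List of matrices sharing row/column names (subsets
#'   allowed; cells are averaged over the cancers where both genes occur).
#' @return List with `mean` (average matrix) and `n` (per-cell cohort
#'   count).
#' @export
average_correlation_matrices <- function(matrices) {
  if (!length(matrices)) stop_validation("no matrices to average")
  genes <- sort(unique(unlist(lapply(matrices, rownames))))
  acc <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  cnt <- acc
  for (m in matrices) {
    g <- rownames(m)
    ok <- !is.na(m)
    acc[g, g] <- acc[g, g] + ifelse(ok, m, 0)
    cnt[g, g] <- cnt[g, g] + ok
  }
  avg <- acc / cnt
  avg[cnt == 0] <- NA_real_
  list(mean = avg, n = cnt)
}

#' Export a consensus network as SIF, GraphML, edge and node tables
#'
#' @param network A `consensus_network`.
#' @param prefix Output path prefix; writes `<prefix>.sif`,
#'   `<prefix>.graphml`, `<prefix>_edges.tsv`, `<prefix>_nodes.tsv`.
#' @return Named character vector of written paths.
#' @export
write_network <- function(network, prefix) {
  if (!inherits(network, "consensus_network")) stop_validation("not a consensus_network")
  paths <- c(sif = paste0(prefix, ".sif"),
             graphml = paste0(prefix, ".graphml"),
             edges = paste0(prefix, "_edges.tsv"),
             nodes = paste0(prefix, "_nodes.tsv"))
  writeLines(sprintf("%s\tcoexpression\t%s", network$edges$gene_a,
                     network$edges$gene_b), paths[["sif"]])
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  write_numeric_tsv(network$edges, "weight", paths[["edges"]])
  utils::write.table(network$nodes, paths[["nodes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}
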