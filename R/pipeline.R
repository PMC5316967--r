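#' @title End-to-end pipeline orchestration
#' @description Runs differential expression, the survival screen,
#'   methylation profiles, stromal scoring, enrichment correlations (with
#'   cross-cancer aggregation) and the consensus network from one
#'   configuration, writing every stage's TSV plus a machine-readable run
#'   manifest. Independent stages continue past a failed stage.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param cohorts Either a directory of cohorts (see [read_cohort_dir()]),
#'   a named list of `cohort_bundle`s, or `NULL` to simulate from
#'   `simulation`.
#' @param simulation Optional [simulation_config()] used when `cohorts` is
#'   `NULL`.
#' @param genes Genes screened by the differential and survival stages.
#' @param reference_gene Housekeeping gene for the differential stage.
#' @param frac,reps Survival resampling parameters.
#' @param methylation_gene Gene profiled by the methylation stage.
#' @param stromal_signature Character vector of stromal signature genes.
#' @param gene_sets Named list (or `gene_set_collection`) for the
#'   enrichment stage.
#' @param seed_genes Two seed genes for enrichment/network stages.
#' @param enrichment_threshold Retention threshold on `|rho|`.
#' @param list_a,list_b Cancer codes for each seed's consensus list
#'   (default: all cohorts).
#' @param edge_cohort Cancer code of the designated edge cohort (default:
#'   first cohort).
#' @param r_threshold,frac_threshold,edge_threshold Network thresholds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohorts = NULL, simulation = NULL,
                            genes = NULL, reference_gene = "TBP",
                            frac = 0.7, reps = 500L,
                            methylation_gene = NULL,
                            stromal_signature = NULL,
                            gene_sets = NULL,
                            seed_genes = c("SFRP2", "SFRP4"),
                            enrichment_threshold = 0.5,
                            list_a = NULL, list_b = NULL,
                            edge_cohort = NULL,
                            r_threshold = 0.5, frac_threshold = 0.5,
                            edge_threshold = 0.8) {
  if (is.null(cohorts) && is.null(simulation))
    stop_validation("either cohorts or a simulation config is required")
  for (thr in c(enrichment_threshold, r_threshold, frac_threshold))
    if (thr < 0 || thr > 1) stop_validation("thresholds must lie in [0, 1]")
  structure(as.list(environment()), class = "pipeline_config")
}

write_stage_tsv <- function(df, path) {
  num <- names(df)[vapply(df, is.numeric, TRUE)]
  write_numeric_tsv(df, num, path)
}

#' Run the full pipeline
#'
#' Executes, in order: tumour-vs-normal differential screen, survival
#' screen, methylation correlation/locus profiles, stromal scores and
#' associations, enrichment correlations per cancer plus a cross-cancer
#' average, and the consensus network. Each stage's table is written under
#' `out_dir` and recorded (status, row count, md5 checksum) in
#' `manifest.json`. Rerunning with the same configuration and seed yields
#' content-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed fanned out deterministically per stage.
#' @param out_dir Output directory.
#' @return Invisible list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(config, seed = 1L, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = seed, stages = list())
  results <- list()

  bundles <-
    if (is.list(config$cohorts) && length(config$cohorts) &&
        inherits(config$cohorts[[1]], "cohort_bundle")) config$cohorts
    else if (is.character(config$cohorts)) read_cohort_dir(config$cohorts)
    else {
      sim_cfg <- unclass(config$simulation)
      sim_cfg$rng_seed <- derive_seed(seed, "simulate")
      sim <- simulate_multicancer(do.call(simulation_config, sim_cfg))
      results$truth <- sim$truth
      sim$bundles
    }
  results$bundles <- bundles
  codes <- vapply(bundles, `[[`, "", "cancer_code")

  genes <- config$genes
  if (is.null(genes)) genes <- config$seed_genes
  record <- function(name, status, path = NA_character_, rows = NA_integer_,
                     note = "") {
    manifest$stages[[name]] <<- list(
      stage = name, status = status, rows = rows,
      file = if (is.na(path)) NULL else basename(path),
      md5 = if (is.na(path)) NULL else unname(tools::md5sum(path)),
      note = note)
  }
  run_stage <- function(name, expr, writer) {
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      record(name, "failed", note = conditionMessage(out))
      return(NULL)
    }
    if (is.null(out)) { record(name, "skipped"); return(NULL) }
    path <- writer(out)
    record(name, "completed", path,
           rows = if (is.data.frame(out)) nrow(out) else NA_integer_)
    out
  }

  results$differential <- run_stage("differential_expression",
    tumour_normal_screen(bundles, genes, config$reference_gene),
    function(df) write_stage_tsv(df, file.path(out_dir, "differential_expression.tsv")))

  results$survival <- run_stage("survival_screen",
    survival_screen(bundles, genes, frac = config$frac, reps = config$reps,
                    seed = derive_seed(seed, "survival")),
    function(df) write_stage_tsv(df, file.path(out_dir, "survival_screen.tsv")))

  results$methylation <- run_stage("methylation", {
    gene <- config$methylation_gene
    with_meth <- Filter(function(b) !is.null(b$methylation), bundles)
    if (is.null(gene) || !length(with_meth)) NULL
    else do.call(rbind, lapply(with_meth, function(b) {
      pr <- probe_expression_correlations(b, gene)
      pr$cancer_code <- b$cancer_code
      pr
    }))
  }, function(df) write_stage_tsv(df, file.path(out_dir, "methylation_correlations.tsv")))

  results$stromal <- run_stage("stromal_scores", {
    if (is.null(config$stromal_signature)) NULL
    else do.call(rbind, lapply(bundles, function(b) {
      sc <- stromal_scores(b, config$stromal_signature)
      assoc <- vapply(genes, function(g)
        tryCatch(stromal_association(b, g, sc), error = function(e) NA_real_), 0)
      data.frame(cancer_code = b$cancer_code, gene = genes,
                 rho = unname(assoc), n = nrow(sc), stringsAsFactors = FALSE)
    }))
  }, function(df) write_stage_tsv(df, file.path(out_dir, "stromal_associations.tsv")))

  results$enrichment <- run_stage("enrichment_correlation", {
    if (is.null(config$gene_sets)) NULL
    else {
      per <- list()
      for (b in bundles) for (sg in config$seed_genes) {
        pr <- enrichment_correlation_profile(b, config$gene_sets, sg,
                                             threshold = config$enrichment_threshold)
        pr$cancer_code <- b$cancer_code; pr$seed_gene <- sg
        per[[length(per) + 1L]] <- pr
      }
      do.call(rbind, per)
    }
  }, function(df) write_stage_tsv(df, file.path(out_dir, "enrichment_correlations.tsv")))

  if (!is.null(results$enrichment)) {
    agg <- aggregate_cross_cancer(results$enrichment, value_col = "rho",
                                  key_cols = c("set", "seed_gene"))
    write_stage_tsv(agg, file.path(out_dir, "enrichment_cross_cancer.tsv"))
    results$enrichment_cross_cancer <- agg
  }

  results$network <- run_stage("consensus_network", {
    list_a <- if (is.null(config$list_a)) codes else config$list_a
    list_b <- if (is.null(config$list_b)) codes else config$list_b
    edge_code <- if (is.null(config$edge_cohort)) codes[[1]] else config$edge_cohort
    prof <- function(code, sg) seedgene_correlation_profile(bundles[[code]], sg)
    pa <- lapply(list_a, prof, sg = config$seed_genes[1])
    pb <- lapply(list_b, prof, sg = config$seed_genes[2])
    members <- consensus_gene_set(pa, pb, config$r_threshold, config$frac_threshold)
    build_network(bundles[[edge_code]], members, config$seed_genes,
                  config$edge_threshold)
  }, function(net) {
    paths <- write_network(net, file.path(out_dir, "consensus_network"))
    paths[["edges"]]
  })

  manifest$parameters <- list(
    genes = genes, reference_gene = config$reference_gene,
    frac = config$frac, reps = config$reps,
    seed_genes = config$seed_genes,
    thresholds = list(enrichment = config$enrichment_threshold,
                      r = config$r_threshold, frac = config$frac_threshold,
                      edge = config$edge_threshold))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}

#' Cross-cancer aggregation of per-cancer correlation tables
#'
#' Elementwise arithmetic mean of a value column over cancers, per key,
#' with the per-cell count of contributing cancers.
#'
#' @param tables Data frame stacking per-cancer rows (must contain
#'   `cancer_code`), or list of such data frames.
#' @param value_col Name of the numeric column to average.
#' @param key_cols Grouping columns.
#' @return Data frame with the keys, `mean_<value_col>` and `n_cancers`.
#' @export
aggregate_cross_cancer <- function(tables, value_col, key_cols) {
  df <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  miss <- setdiff(c(value_col, key_cols), names(df))
  if (length(miss)) stop_validation("missing column(s): ", paste(miss, collapse = ", "))
  agg_mean <- stats::aggregate(df[[value_col]], df[key_cols],
                               function(v) mean(v, na.rm = TRUE))
  agg_n <- stats::aggregate(df[[value_col]], df[key_cols],
                            function(v) sum(!is.na(v)))
  out <- agg_mean
  names(out)[ncol(out)] <- paste0("mean_", value_col)
  out$n_cancers <- as.integer(agg_n$x)
  out <- out[do.call(order, out[key_cols]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
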