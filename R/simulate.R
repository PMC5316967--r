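#' @title Synthetic multi-cancer cohort generator
#' @description Generates TCGA-like cohorts with planted structure so each
#'   downstream stage has a parameter-recovery test: a latent per-sample
#'   stromal fraction drives a correlated stromal/EMT gene program containing
#'   two seed genes; one gene is methylation-silenced (expression inversely
#'   tied to promoter beta values); survival hazard depends on standardized
#'   program activity.
#' @name synthetic-cohort
NULL

#' Simulation configuration
#'
#' Defaults define the reference study conditions: 6 cancers, 300 primary
#' tumours and 50 normals each, a 50-gene stromal program (loadings 1.0 on
#' the standardized stromal fraction, log2-scale noise SD 0.5) containing the
#' two seed genes, one methylation-silenced gene with 8 promoter probes and a
#' log2-expression drop of 4 per unit promoter beta, and exponential survival
#' with a log hazard ratio of log(2) per unit standardized program activity
#' under 30% uniform censoring.
#'
#' @param n_cancers Number of cohorts to simulate.
#' @param n_tumour,n_normal,n_metastatic Samples per cohort by tissue type.
#' @param n_genes Total genes (program + silenced + reference + background).
#' @param seed_genes Two designated program genes.
#' @param silenced_gene Methylation-controlled gene.
#' @param reference_gene Housekeeping gene (loading 0, low noise).
#' @param n_program_genes Program size, seed genes included.
#' @param program_loading Loading of each program gene on the standardized
#'   stromal fraction (scalar or vector of length `n_program_genes`),
#'   log2-expression units per SD of stromal fraction.
#' @param stromal_alpha,stromal_beta Beta-distribution parameters of the
#'   tumour stromal fraction `s` in `[0, 1]`.
#' @param normal_stromal_alpha,normal_stromal_beta Beta parameters of the
#'   (lower, tighter) normal-tissue stromal fraction.
#' @param noise_sd Log2-scale Gaussian noise SD.
#' @param promoter_probe_count,nonpromoter_probe_count CpG probes at the
#'   silenced gene's locus; promoter probes carry the silencing signal.
#' @param meth_slope Log2-expression change per unit mean promoter beta
#'   (negative = silencing).
#' @param survival_baseline_rate Baseline hazard, events/day.
#' @param survival_log_hr Planted log hazard ratio per unit standardized
#'   program activity.
#' @param censor_rate Expected censored fraction, in `[0, 1)`.
#' @param rng_seed Integer seed; the full output is reproducible from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_cancers = 6L,
                              n_tumour = 300L,
                              n_normal = 50L,
                              n_metastatic = 0L,
                              n_genes = 200L,
                              seed_genes = c("SFRP2", "SFRP4"),
                              silenced_gene = "SFRP1",
                              reference_gene = "TBP",
                              n_program_genes = 50L,
                              program_loading = 1.0,
                              stromal_alpha = 2,
                              stromal_beta = 2,
                              normal_stromal_alpha = 4,
                              normal_stromal_beta = 12,
                              noise_sd = 0.5,
                              promoter_probe_count = 8L,
                              nonpromoter_probe_count = 12L,
                              meth_slope = -4,
                              survival_baseline_rate = 1 / 1000,
                              survival_log_hr = log(2),
                              censor_rate = 0.3,
                              rng_seed = 1L) {
  cfg <- list(n_cancers = as.integer(n_cancers), n_tumour = as.integer(n_tumour),
              n_normal = as.integer(n_normal), n_metastatic = as.integer(n_metastatic),
              n_genes = as.integer(n_genes), seed_genes = seed_genes,
              silenced_gene = silenced_gene, reference_gene = reference_gene,
              n_program_genes = as.integer(n_program_genes),
              program_loading = program_loading,
              stromal_alpha = stromal_alpha, stromal_beta = stromal_beta,
              normal_stromal_alpha = normal_stromal_alpha,
              normal_stromal_beta = normal_stromal_beta,
              noise_sd = noise_sd,
              promoter_probe_count = as.integer(promoter_probe_count),
              nonpromoter_probe_count = as.integer(nonpromoter_probe_count),
              meth_slope = meth_slope,
              survival_baseline_rate = survival_baseline_rate,
              survival_log_hr = survival_log_hr,
              censor_rate = censor_rate, rng_seed = as.integer(rng_seed))
  if (length(cfg$seed_genes) != 2L) stop_validation("exactly two seed genes required")
  if (cfg$n_program_genes < 2L) stop_validation("program must contain the seed genes")
  if (cfg$stromal_alpha <= 0 || cfg$stromal_beta <= 0 ||
      cfg$normal_stromal_alpha <= 0 || cfg$normal_stromal_beta <= 0)
    stop_validation("Beta parameters of the stromal fraction must be positive")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop_validation("censor_rate must lie in [0, 1)")
  if (any(!is.finite(cfg$program_loading)))
    stop_validation("program loadings must be finite")
  if (cfg$noise_sd < 0) stop_validation("noise_sd must be non-negative")
  if (cfg$survival_baseline_rate <= 0) stop_validation("baseline rate must be positive")
  n_fixed <- cfg$n_program_genes + 2L  # program (incl. seeds) + silenced + reference
  if (cfg$n_genes < n_fixed)
    stop_validation("n_genes must be at least ", n_fixed)
  ld <- cfg$program_loading
  if (!length(ld) %in% c(1L, cfg$n_program_genes))
    stop_validation("program_loading must be scalar or one per program gene")
  class(cfg) <- "simulation_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror [simulation_config()] arguments; absent keys keep defaults.
#'
#' @param path YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_format("unknown simulation config key(s): ", paste(unknown, collapse = ", "))
  do.call(simulation_config, vals)
}

gene_panel <- function(cfg) {
  program <- c(cfg$seed_genes,
               sprintf("PRG%03d", seq_len(cfg$n_program_genes - 2L)))
  n_bg <- cfg$n_genes - cfg$n_program_genes - 2L
  background <- if (n_bg > 0) sprintf("BGD%03d", seq_len(n_bg)) else character()
  list(program = program,
       all = c(program, cfg$silenced_gene, cfg$reference_gene, background),
       background = background)
}

#' Simulate survival times under a proportional-hazards model
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(log_hr * covariate)`; censoring is independent
#' uniform on `[0, C]` with `C` calibrated numerically so the expected
#' censored fraction equals `censor_rate`.
#'
#' @param n Number of subjects (>= 2).
#' @param covariate Numeric covariate vector of length `n`.
#' @param log_hr Log hazard ratio per covariate unit.
#' @param baseline_rate Baseline hazard, events/day (> 0).
#' @param censor_rate Expected censored fraction in `[0, 1)`.
#' @param seed Optional integer seed for reproducibility.
#' @param sample_ids Optional sample identifiers (default `S1..Sn`).
#' @return A clinical data frame (`sample_id`, `os_time`, `os_event`).
#' @export
simulate_survival <- function(n, covariate, log_hr, baseline_rate,
                              censor_rate = 0, seed = NULL, sample_ids = NULL) {
  if (n < 2L) stop_validation("n must be >= 2")
  if (length(covariate) != n) stop_validation("covariate length must equal n")
  if (baseline_rate <= 0) stop_validation("baseline_rate must be positive")
  if (censor_rate < 0 || censor_rate >= 1) stop_validation("censor_rate must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  rate <- baseline_rate * exp(log_hr * covariate)
  t_event <- stats::rexp(n, rate)
  if (censor_rate > 0) {
    # P(U < T) for U ~ Unif(0, C), T ~ Exp(rate_i): (1 - exp(-rate_i C)) / (rate_i C)
    cens_frac <- function(C) mean((1 - exp(-rate * C)) / (rate * C)) - censor_rate
    upper <- 1 / min(rate)
    while (cens_frac(upper) > 0) upper <- upper * 4
    C <- stats::uniroot(cens_frac, c(1e-9 / max(rate), upper), tol = 1e-10)$root
    u <- stats::runif(n, 0, C)
    os_time <- pmin(t_event, u)
    os_event <- as.integer(t_event <= u)
  } else {
    os_time <- t_event
    os_event <- rep(1L, n)
  }
  os_time <- pmax(os_time, .Machine$double.eps)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(n))
  data.frame(sample_id = sample_ids, os_time = os_time, os_event = os_event,
             stringsAsFactors = FALSE)
}

simulate_one_cohort <- function(cfg, code, cohort_seed) {
  set.seed(cohort_seed)
  panel <- gene_panel(cfg)
  ids_t <- sprintf("%s-T%03d", code, seq_len(cfg$n_tumour))
  ids_n <- if (cfg$n_normal > 0) sprintf("%s-N%03d", code, seq_len(cfg$n_normal)) else character()
  ids_m <- if (cfg$n_metastatic > 0) sprintf("%s-M%03d", code, seq_len(cfg$n_metastatic)) else character()
  ids <- c(ids_t, ids_n, ids_m)
  n_all <- length(ids)

  # latent stromal fraction; tumour standardization defines program activity
  s_t <- stats::rbeta(cfg$n_tumour, cfg$stromal_alpha, cfg$stromal_beta)
  s_n <- if (cfg$n_normal > 0)
    stats::rbeta(cfg$n_normal, cfg$normal_stromal_alpha, cfg$normal_stromal_beta) else numeric()
  s_m <- if (cfg$n_metastatic > 0)
    stats::rbeta(cfg$n_metastatic, cfg$stromal_alpha, cfg$stromal_beta) else numeric()
  s <- stats::setNames(c(s_t, s_n, s_m), ids)
  mu_s <- mean(s_t); sd_s <- stats::sd(s_t)
  if (!is.finite(sd_s) || sd_s == 0) sd_s <- 1
  z <- (s - mu_s) / sd_s  # standardized program activity (tumour scale)

  loadings <- rep(cfg$program_loading, length.out = cfg$n_program_genes)
  names(loadings) <- panel$program
  baselines <- stats::setNames(stats::runif(length(panel$all), 4, 10), panel$all)
  baselines[cfg$reference_gene] <- 6

  logexpr <- matrix(0, nrow = length(panel$all), ncol = n_all,
                    dimnames = list(panel$all, ids))
  for (g in panel$program)
    logexpr[g, ] <- baselines[g] + loadings[g] * z +
      stats::rnorm(n_all, 0, cfg$noise_sd)
  for (g in panel$background)
    logexpr[g, ] <- baselines[g] + stats::rnorm(n_all, 0, cfg$noise_sd)
  logexpr[cfg$reference_gene, ] <- baselines[cfg$reference_gene] +
    stats::rnorm(n_all, 0, 0.2)

  # methylation: per-sample promoter methylation level, high in tumours
  n_probes <- cfg$promoter_probe_count + cfg$nonpromoter_probe_count
  m_level <- stats::setNames(numeric(n_all), ids)
  m_level[ids_t] <- stats::rbeta(cfg$n_tumour, 8, 2)
  if (length(ids_n)) m_level[ids_n] <- stats::rbeta(cfg$n_normal, 2, 8)
  if (length(ids_m)) m_level[ids_m] <- stats::rbeta(cfg$n_metastatic, 8, 2)

  meth <- NULL
  promoter_probes <- character()
  if (n_probes > 0) {
    probe_ids <- sprintf("cg%05d", seq_len(n_probes))
    promoter_probes <- probe_ids[seq_len(cfg$promoter_probe_count)]
    beta <- matrix(NA_real_, nrow = n_probes, ncol = n_all,
                   dimnames = list(probe_ids, ids))
    for (p in seq_len(n_probes)) {
      if (p <= cfg$promoter_probe_count) {
        beta[p, ] <- pmin(pmax(m_level + stats::rnorm(n_all, 0, 0.05), 0), 1)
      } else {
        beta[p, ] <- stats::rbeta(n_all, 2, 2)
      }
    }
    meth <- methylation_matrix(beta,
      data.frame(probe_id = probe_ids, position = 500L * seq_len(n_probes),
                 gene = cfg$silenced_gene, stringsAsFactors = FALSE))
    mean_prom_beta <- colMeans(beta[promoter_probes, , drop = FALSE])
  } else {
    mean_prom_beta <- m_level
  }
  logexpr[cfg$silenced_gene, ] <- baselines[cfg$silenced_gene] +
    cfg$meth_slope * mean_prom_beta + stats::rnorm(n_all, 0, cfg$noise_sd)

  expr <- pmax(2^logexpr - 1, 0)

  ann <- data.frame(sample_id = ids, cancer_code = code,
                    tissue_type = rep(c("primary", "normal", "metastatic"),
                                      c(length(ids_t), length(ids_n), length(ids_m))),
                    stringsAsFactors = FALSE)
  clinical <- simulate_survival(cfg$n_tumour, z[ids_t], cfg$survival_log_hr,
                                cfg$survival_baseline_rate, cfg$censor_rate,
                                seed = NULL, sample_ids = ids_t)
  bundle <- cohort_bundle(code, expr, ann, clinical, meth)
  list(bundle = bundle,
       truth = list(stromal_fraction = s, program_activity = z,
                    loadings = loadings, promoter_probes = promoter_probes,
                    mean_promoter_beta = mean_prom_beta))
}

#' Simulate a multi-cancer cohort collection with planted truth
#'
#' @param config A [simulation_config()].
#' @return List with `bundles` (named list of `cohort_bundle`s) and `truth`
#'   (class `planted_truth`): per-cancer latent stromal fractions and program
#'   activities, the program gene list with loadings, the planted log hazard
#'   ratio, methylation slope and promoter probe ids.
#' @export
simulate_multicancer <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  codes <- sprintf("SIM%02d", seq_len(config$n_cancers))
  per <- lapply(seq_along(codes), function(i)
    simulate_one_cohort(config, codes[i], derive_seed(config$rng_seed, i)))
  bundles <- stats::setNames(lapply(per, `[[`, "bundle"), codes)
  panel <- gene_panel(config)
  truth <- structure(list(
    config = config,
    cancer_codes = codes,
    program_genes = panel$program,
    loadings = per[[1]]$truth$loadings,
    log_hr = config$survival_log_hr,
    meth_slope = config$meth_slope,
    promoter_probes = per[[1]]$truth$promoter_probes,
    stromal_fraction = lapply(stats::setNames(per, codes),
                              function(p) p$truth$stromal_fraction),
    program_activity = lapply(stats::setNames(per, codes),
                              function(p) p$truth$program_activity)),
    class = "planted_truth")
  list(bundles = bundles, truth = truth)
}

#' Planted-truth versus achieved-statistics report
#'
#' For one generated bundle, tabulates each planted parameter next to the
#' achievable sample statistic, for use in recovery tests.
#'
#' @param truth A `planted_truth` from [simulate_multicancer()].
#' @param bundle One of the matching generated bundles.
#' @return Data frame with columns `quantity`, `planted`, `achieved`.
#' @export
truth_report <- function(truth, bundle) {
  if (!inherits(truth, "planted_truth")) stop_validation("not a planted_truth")
  code <- bundle$cancer_code
  if (!code %in% truth$cancer_codes)
    stop_validation("bundle cohort ", code, " not described by this truth object")
  s <- truth$stromal_fraction[[code]]
  if (!setequal(names(s), colnames(bundle$expression)))
    stop_validation("sample sets of truth and bundle do not match")
  tum <- samples_of(bundle, "primary")
  le <- log2_plus_one(bundle$expression)
  sg <- truth$config$seed_genes
  rows <- list(
    c("log_hr", truth$log_hr, NA),
    c("meth_slope", truth$meth_slope, NA),
    c("seed_loading_a", unname(truth$loadings[sg[1]]),
      pearson_correlation(le[sg[1], tum], s[tum])),
    c("seed_loading_b", unname(truth$loadings[sg[2]]),
      pearson_correlation(le[sg[2], tum], s[tum])),
    c("seed_pair_r", NA, pearson_correlation(le[sg[1], tum], le[sg[2], tum])))
  if (!is.null(bundle$methylation)) {
    pb <- truth$promoter_probes
    mean_beta <- colMeans(bundle$methylation$beta[pb, tum, drop = FALSE], na.rm = TRUE)
    rows <- c(rows, list(c("promoter_beta_expr_r", sign(truth$meth_slope),
                           pearson_correlation(mean_beta,
                                               le[truth$config$silenced_gene, tum]))))
  }
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r)
    data.frame(quantity = r[1], planted = as.numeric(r[2]),
               achieved = as.numeric(r[3]), stringsAsFactors = FALSE))))
  df
}
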