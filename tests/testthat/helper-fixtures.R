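# Shared fixture builders and independent oracles used across test files.

# Small hand-built cohort: 3 genes x 4 samples (+ optional methylation).
toy_bundle <- function(with_methylation = TRUE) {
  expr <- matrix(c(10, 5, 2, 8,
                   4, 2, 1, 4,
                   5, 5, 5, 5),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("GENEA", "GENEB", "TBP"),
                                 c("S1", "S2", "S3", "S4")))
  ann <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                    cancer_code = "TOY",
                    tissue_type = c("normal", "primary", "primary", "metastatic"),
                    stringsAsFactors = FALSE)
  cl <- data.frame(sample_id = c("S2", "S3"), os_time = c(100, 250),
                   os_event = c(1, 0), stringsAsFactors = FALSE)
  meth <- NULL
  if (with_methylation) {
    beta <- matrix(c(0.1, 0.8, 0.9, 0.5,
                     0.2, 0.7, NA, 0.4),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("cg01", "cg02"), c("S1", "S2", "S3", "S4")))
    meth <- methylation_matrix(beta,
      data.frame(probe_id = c("cg01", "cg02"), position = c(100L, 200L),
                 gene = "GENEA", stringsAsFactors = FALSE))
  }
  cohort_bundle("TOY", expr, ann, cl, meth)
}

# Small generator config for fast recovery tests; dots override defaults.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_cancers = 1L, n_tumour = 120L, n_normal = 30L, n_genes = 60L,
         n_program_genes = 20L, rng_seed = 101L),
    list(...))
  do.call(simulation_config, args)
}

# Textbook-formula correlation oracles (kept independent of the package's
# cor-based implementations).
pearson_oracle <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
spearman_oracle <- function(x, y) pearson_oracle(rank(x), rank(y))

# Exhaustive Youden-cutoff oracle: double loop over every midpoint
# threshold and both test-positive directions.
youden_oracle <- function(values, events) {
  v <- sort(unique(values))
  thr <- (v[-length(v)] + v[-1]) / 2
  best <- list(j = -Inf, cutoff = NA)
  for (t in thr) {
    for (dir in c("high", "low")) {
      pos <- if (dir == "high") values > t else values <= t
      sens <- sum(pos & events == 1) / sum(events == 1)
      spec <- sum(!pos & events == 0) / sum(events == 0)
      j <- sens + spec - 1
      if (j > best$j + 1e-12) best <- list(j = j, cutoff = t)
    }
  }
  best
}

# Full-enumeration Mann-Whitney oracle (tie-free inputs): U for every
# labeling of the pooled sample, two-sided tail doubling.
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  u_null <- apply(utils::combn(length(pooled), nx), 2, u_of)
  p <- min(1, 2 * min(mean(u_null <= u_obs), mean(u_null >= u_obs)))
  list(u = u_obs, p_value = p)
}

# Efron partial log-likelihood, vectorized over a beta grid; independent of
# survival::coxph.
efron_loglik <- function(beta_grid, time, status, x) {
  ll <- numeric(length(beta_grid))
  ex <- exp(outer(beta_grid, x))  # grid x subjects
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- rowSums(ex[, R, drop = FALSE])
    sum_d <- rowSums(ex[, D, drop = FALSE])
    ll <- ll + beta_grid * sum(x[D])
    for (l in seq_len(d) - 1L) ll <- ll - log(sum_r - (l / d) * sum_d)
  }
  ll
}

# Textbook two-group log-rank statistic (O - E with hypergeometric variance).
logrank_oracle <- function(time, status, group) {
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[status == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Fake correlation profile (as seedgene_correlation_profile would emit) for
# consensus-rule tests.
fake_profile <- function(code, seed_gene, genes, r) {
  out <- data.frame(gene = genes, r = r, stringsAsFactors = FALSE)
  attr(out, "cancer_code") <- code
  attr(out, "seed_gene") <- seed_gene
  out
}

# Brute-force consensus oracle: nested loops over genes and cancers.
consensus_oracle <- function(profiles_a, profiles_b, r_thr = 0.5, f_thr = 0.5) {
  genes <- sort(unique(c(unlist(lapply(profiles_a, `[[`, "gene")),
                         unlist(lapply(profiles_b, `[[`, "gene")))))
  seeds <- unique(c(sapply(profiles_a, attr, "seed_gene"),
                    sapply(profiles_b, attr, "seed_gene")))
  keep <- character()
  for (g in genes) {
    passes <- function(profiles) {
      hits <- 0
      for (p in profiles) {
        r <- p$r[match(g, p$gene)]
        if (!is.na(r) && r > r_thr) hits <- hits + 1
      }
      hits / length(profiles) >= f_thr
    }
    if (passes(profiles_a) && passes(profiles_b)) keep <- c(keep, g)
  }
  sort(setdiff(keep, seeds))
}
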