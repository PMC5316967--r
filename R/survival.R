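#' @title Optimal-cutpoint survival screening
#' @description ROC/Youden dichotomization of expression, Kaplan-Meier,
#'   log-rank and univariate Cox regression (Efron ties), plus a
#'   70%-subsample x 500 resampling robustness screen.
#' @name survival-analysis
NULL

#' Optimal dichotomization cutoff by the Youden index
#'
#' Candidate thresholds are midpoints between consecutive distinct sorted
#' values. With "positive" meaning `event == 1`, the test-positive side
#' (value above or below the threshold) is chosen so that
#' J = sensitivity + specificity - 1 is non-negative, and the threshold
#' maximizing J is returned; ties are broken by the smallest qualifying
#' threshold.
#'
#' @param values Numeric marker values (at least 2 distinct).
#' @param events Binary outcome labels (both classes present).
#' @return List with `cutoff`, `j` and `direction` (`"high"` if the
#'   above-threshold group is event-enriched at the chosen cutoff).
#' @export
youden_cutoff <- function(values, events) {
  if (length(values) != length(events)) stop_validation("length mismatch")
  if (length(unique(events)) != 2L || !all(events %in% c(0, 1)))
    stop_validation("both event classes (0 and 1) must be present")
  v <- sort(unique(values))
  if (length(v) < 2L) stop_validation("need at least 2 distinct values")
  thr <- (v[-length(v)] + v[-1]) / 2
  n_pos <- sum(events == 1); n_neg <- sum(events == 0)
  # J for test-positive = value > threshold, on the integer lattice so that
  # ties between thresholds (and between directions) are exact:
  # J_high * n_pos * n_neg = a*n_neg + b*n_pos - n_pos*n_neg
  a <- vapply(thr, function(t) sum(values > t & events == 1), 0)
  b <- vapply(thr, function(t) sum(values <= t & events == 0), 0)
  j_scaled <- a * n_neg + b * n_pos - n_pos * n_neg
  j_abs <- abs(j_scaled)  # flipping the test-positive side negates J
  best <- which(j_abs == max(j_abs))[1]  # thresholds ascending: first = smallest
  list(cutoff = thr[best], j = j_abs[best] / (n_pos * n_neg),
       direction = if (j_scaled[best] >= 0) "high" else "low")
}

#' Kaplan-Meier product-limit curve
#'
#' @param times Positive event/censoring times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Data frame with `time`, `n_risk`, `n_event`, `survival`;
#'   survival starts at 1 and is non-increasing.
#' @export
km_curve <- function(times, events) {
  if (!length(times)) stop_validation("empty input")
  if (any(times <= 0)) stop_validation("times must be positive")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             survival = sf$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic with hypergeometric variance,
#' referred to a chi-square distribution with 1 degree of freedom.
#'
#' @param times Positive times.
#' @param events Event indicators.
#' @param group Two-level group labels, both levels non-empty.
#' @return List with `chi2` and `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2L)
    stop_validation("exactly two non-empty groups required")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  chi2 <- sd$chisq
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Univariate Cox regression on a binary group
#'
#' Partial-likelihood fit with Efron tie handling. Monotone likelihood
#' (complete separation of event orderings) is detected and reported as
#' non-estimable rather than as a huge finite hazard ratio.
#'
#' @param times Positive times.
#' @param events Event indicators with at least one event.
#' @param group Binary group (coded so that the returned hazard ratio is
#'   group 1 versus group 0); both levels must be present.
#' @param ties Tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return List with `hazard_ratio`, `ci_low`, `ci_high`, `wald_p`, `beta`,
#'   `se` and `estimable`.
#' @export
cox_univariate <- function(times, events, group, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  g <- as.numeric(group)
  if (length(unique(g)) != 2L) stop_validation("group must have exactly two levels")
  if (sum(events) < 1) stop_validation("at least one event required")
  infinite_warn <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ g, ties = ties,
                    control = survival::coxph.control(eps = 1e-10, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) infinite_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))[1]
  estimable <- is.finite(beta) && is.finite(se) && !infinite_warn && abs(beta) < 10
  if (!estimable)
    return(list(hazard_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                wald_p = NA_real_, beta = beta, se = se, estimable = FALSE))
  z <- beta / se
  list(hazard_ratio = exp(beta),
       ci_low = exp(beta - 1.96 * se),
       ci_high = exp(beta + 1.96 * se),
       wald_p = 2 * stats::pnorm(-abs(z)),
       beta = beta, se = se, estimable = TRUE)
}

#' Subsample-resampled Cox screen for robustness
#'
#' Repeats the dichotomize-then-fit analysis on random subsamples drawn
#' without replacement: each replicate takes `floor(frac * n)` samples,
#' re-derives the Youden cutoff and refits the univariate Cox model.
#' Defaults follow the screen's reference conditions: 70% subsamples, 500
#' replicates.
#'
#' @param times,events Survival data.
#' @param values Marker values dichotomized per replicate.
#' @param frac Subsample fraction in (0, 1].
#' @param reps Number of replicates.
#' @param seed Optional integer seed.
#' @return List with `median_hr` (median over estimable replicates),
#'   `frac_concordant` (fraction of estimable replicates whose hazard ratio
#'   falls on the same side of 1 as the full-data fit), `hr` (per-replicate
#'   hazard ratios, `NA` where non-estimable), `n_failed` and `flagged`
#'   (more than half the replicates unusable).
#' @export
resample_cox <- function(times, events, values, frac = 0.7, reps = 500L,
                         seed = NULL) {
  if (frac <= 0 || frac > 1) stop_validation("frac must lie in (0, 1]")
  if (reps < 1L) stop_validation("reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- length(times)
  m <- max(2L, floor(frac * n))
  full <- fit_dichotomized_cox(times, events, values)
  full_hr <- if (full$estimable) full$hazard_ratio else NA_real_
  hr <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, m)
    fitr <- tryCatch(fit_dichotomized_cox(times[idx], events[idx], values[idx]),
                     error = function(e) NULL)
    if (!is.null(fitr) && fitr$estimable) hr[r] <- fitr$hazard_ratio
  }
  n_failed <- sum(is.na(hr))
  conc <- if (is.na(full_hr)) NA_real_
          else mean(sign(log(hr[!is.na(hr)])) == sign(log(full_hr)))
  list(median_hr = stats::median(hr, na.rm = TRUE),
       frac_concordant = conc, hr = hr, n_failed = n_failed,
       flagged = n_failed > reps / 2)
}

# One dichotomize-then-fit pass: Youden cutoff on (values, events), then Cox
# on high (value > cutoff) versus low.
fit_dichotomized_cox <- function(times, events, values, min_group = 1L) {
  yc <- youden_cutoff(values, events)
  high <- as.integer(values > yc$cutoff)
  if (min(sum(high), sum(!high)) < min_group)
    return(list(estimable = FALSE, hazard_ratio = NA_real_, cutoff = yc$cutoff,
                j = yc$j, n_high = sum(high), n_low = sum(!high)))
  fit <- cox_univariate(times, events, high)
  c(fit, list(cutoff = yc$cutoff, j = yc$j,
              n_high = sum(high), n_low = sum(!high)))
}

#' Pan-cohort survival screen (forest table)
#'
#' Per (gene, cancer): primary-tumour expression on the RSEM-normalized
#' scale is dichotomized at the Youden-optimal cutoff, the high
#' (above-cutoff) versus low groups are compared by log-rank test and
#' univariate Cox regression, and robustness is assessed by subsample
#' resampling. Rows where either dichotomized arm has fewer than `min_group`
#' samples, or where any step fails, are flagged and the screen continues.
#'
#' @param bundles List of `cohort_bundle`s with clinical data.
#' @param genes Gene symbols to screen.
#' @param frac,reps Resampling parameters (defaults 0.7 and 500).
#' @param seed Integer seed fanned out per (gene, cancer).
#' @param min_group Minimum samples per dichotomized arm (default 5).
#' @return Data frame sorted by cancer then gene with cutoff, Youden J,
#'   group sizes, hazard ratio with 95% CI, Wald and log-rank p-values and
#'   resampling summaries.
#' @export
survival_screen <- function(bundles, genes, frac = 0.7, reps = 500L,
                            seed = 1L, min_group = 5L) {
  rows <- list()
  for (b in bundles) {
    code <- b$cancer_code
    tum <- samples_of(b, "primary")
    cl <- b$clinical[b$clinical$sample_id %in% tum, , drop = FALSE]
    for (g in genes) {
      row <- data.frame(gene = g, cancer_code = code, n = nrow(cl),
                        cutoff = NA_real_, youden_j = NA_real_,
                        n_high = NA_integer_, n_low = NA_integer_,
                        hazard_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, wald_p = NA_real_,
                        logrank_p = NA_real_, resample_median_hr = NA_real_,
                        resample_frac_concordant = NA_real_,
                        flagged = TRUE, note = "", stringsAsFactors = FALSE)
      res <- tryCatch({
        if (!g %in% rownames(b$expression)) stop_validation("gene absent")
        if (nrow(cl) < 2L * min_group) stop_validation("too few clinical samples")
        vals <- b$expression[g, cl$sample_id]
        yc <- youden_cutoff(vals, cl$os_event)
        high <- as.integer(vals > yc$cutoff)
        row$cutoff <- yc$cutoff; row$youden_j <- yc$j
        row$n_high <- sum(high); row$n_low <- sum(high == 0)
        if (min(row$n_high, row$n_low) < min_group)
          stop_validation("dichotomized arm below ", min_group, " samples")
        fit <- cox_univariate(cl$os_time, cl$os_event, high)
        lr <- logrank_test(cl$os_time, cl$os_event, high)
        rs <- resample_cox(cl$os_time, cl$os_event, vals, frac = frac,
                           reps = reps,
                           seed = derive_seed(seed, paste0(code, ":", g)))
        row$hazard_ratio <- fit$hazard_ratio
        row$ci_low <- fit$ci_low; row$ci_high <- fit$ci_high
        row$wald_p <- fit$wald_p; row$logrank_p <- lr$p_value
        row$resample_median_hr <- rs$median_hr
        row$resample_frac_concordant <- rs$frac_concordant
        row$flagged <- !fit$estimable || rs$flagged
        if (!fit$estimable) row$note <- "non-estimable (separation)"
        row
      }, error = function(e) { row$note <- conditionMessage(e); row })
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop_validation("no (gene, cancer) combinations to screen")
  out <- do.call(rbind, rows)
  out[order(out$cancer_code, out$gene), , drop = FALSE]
}
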