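#' @title Tumour-versus-normal differential expression
#' @name differential-expression
NULL

#' Mann-Whitney U test (two-sided)
#'
#' The U statistic counts pairs with `x_i > y_j`, plus half a count per tie.
#' The p-value is exact (full enumeration of the null distribution) when the
#' smaller sample has at most 8 observations and the pooled data are
#' tie-free; otherwise the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `u`, `p_value` and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop_validation("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  # U from the rank sum of x: U = R_x - nx(nx+1)/2 counts x>y pairs + half-ties
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(nx, ny) <= 8L && !ties) {
    # exact two-sided tail doubling on the symmetric null distribution of U
    lo <- stats::pwilcox(u, nx, ny)
    hi <- 1 - stats::pwilcox(u - 1, nx, ny)
    p <- min(1, 2 * min(lo, hi))
    method <- "exact"
  } else {
    n <- nx + ny
    mu <- nx * ny / 2
    tab <- table(c(x, y))
    tie_term <- sum(tab^3 - tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- u - mu
      z <- (d - sign(d) * 0.5) / sqrt(sigma2)
      if (d == 0) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(u = u, p_value = p, method = method)
}

#' Tumour-versus-normal screen across cohorts
#'
#' Per (gene, cancer): expression is normalized to a housekeeping reference
#' gene, normal and primary samples are compared by two-sided Mann-Whitney U
#' test, and medians on the reference-normalized scale are reported. Cohorts
#' lacking either tissue group yield rows flagged `skipped`. A
#' Benjamini-Hochberg adjusted p-value is included as a supplementary column;
#' the `significant` flag uses the unadjusted p at `alpha`.
#'
#' @param bundles List of `cohort_bundle`s.
#' @param genes Gene symbols to screen.
#' @param reference_gene Housekeeping gene for normalization.
#' @param alpha Significance level for the flag (default 0.05).
#' @return Data frame, one row per (gene, cancer).
#' @export
tumour_normal_screen <- function(bundles, genes, reference_gene = "TBP",
                                 alpha = 0.05) {
  rows <- list()
  for (b in bundles) {
    code <- b$cancer_code
    norm_expr <- tryCatch(normalize_to_reference_gene(b$expression, reference_gene),
                          error = function(e) e)
    for (g in genes) {
      row <- data.frame(gene = g, cancer_code = code, n_normal = NA_integer_,
                        n_tumour = NA_integer_, median_normal = NA_real_,
                        median_tumour = NA_real_, direction = NA_character_,
                        u_statistic = NA_real_, p_value = NA_real_,
                        skipped = TRUE, note = "", stringsAsFactors = FALSE)
      if (inherits(norm_expr, "error")) {
        row$note <- conditionMessage(norm_expr)
        rows[[length(rows) + 1L]] <- row; next
      }
      if (!g %in% rownames(norm_expr)) {
        row$note <- "gene absent"
        rows[[length(rows) + 1L]] <- row; next
      }
      kept <- colnames(norm_expr)
      nrm <- intersect(samples_of(b, "normal"), kept)
      tum <- intersect(samples_of(b, "primary"), kept)
      row$n_normal <- length(nrm); row$n_tumour <- length(tum)
      if (!length(nrm) || !length(tum)) {
        row$note <- "missing tissue group"
        rows[[length(rows) + 1L]] <- row; next
      }
      vn <- norm_expr[g, nrm]; vt <- norm_expr[g, tum]
      mw <- mann_whitney_u(vt, vn)
      row$median_normal <- stats::median(vn)
      row$median_tumour <- stats::median(vt)
      row$direction <- if (row$median_tumour > row$median_normal) "up"
                       else if (row$median_tumour < row$median_normal) "down"
                       else "unchanged"
      row$u_statistic <- mw$u
      row$p_value <- mw$p_value
      row$skipped <- FALSE
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) stop_validation("no (gene, cancer) combinations to screen")
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_adjusted[ok] <- stats::p.adjust(out$p_value[ok], method = "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out[order(out$cancer_code, out$gene), , drop = FALSE]
}
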