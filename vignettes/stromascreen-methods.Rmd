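---
title: "Methods: pan-cancer seed-gene characterization with stromascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer seed-gene characterization with stromascreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromascreen)
```

# The analysis

`stromascreen` packages a pan-cancer characterization workflow for a small
set of candidate ("seed") genes across many tumour cohorts. The motivating
biology is the secreted Frizzled-related protein family: genes that can be
epigenetically silenced in tumour cells (a tumour-suppressor signature) or
contributed by the tumour stroma (an EMT/matricellular signature), two
situations that bulk expression data easily conflate. The pipeline separates
them with six coordinated analyses per cohort:

1. **Tumour-vs-normal differential expression** of each gene, on
   housekeeping-normalized abundances, by two-sided Mann-Whitney U test.
2. **Survival screening**: expression dichotomized at the ROC/Youden-optimal
   cutoff, then Kaplan-Meier curves, log-rank test, univariate Cox
   regression, and a 70%-subsample x 500 resampling robustness assessment.
3. **Promoter methylation**: per-CpG correlation of beta values with
   log2(expression + 1), plus locus-level group profiles (mean +/- SEM).
4. **Stromal scoring**: a single-sample rank-weighted enrichment (ssGSEA) of
   a stromal signature per tumour, correlated to gene expression by Spearman
   rank correlation.
5. **Per-sample gene-set enrichment** against a formulated mean reference
   sample (a GAGE-style two-sample t statistic of in-set versus background
   fold changes), correlated to seed-gene expression.
6. **Consensus co-expression network**: genes correlated (Pearson r > 0.5 on
   log2 scale) with *both* seed genes in at least 50% of each seed's cancer
   list, with edges drawn where pairwise correlation exceeds 0.8 in one
   designated cohort.

All expression analyses use the `log2(x + 1)` transform of RSEM-like
non-negative abundances, except the differential stage, which first
normalizes to a housekeeping reference gene (default `TBP`) and works on
that ratio scale, and the survival stage, which dichotomizes the raw
RSEM-scale values (rank-based cutoffs are unaffected by monotone rescaling).

# The synthetic cohort generator

Because the original cohorts are large external downloads, every stage is
validated against a generator (`simulate_multicancer()`) that plants the
structure the pipeline is meant to detect.

**Latent stromal program.** Each tumour sample draws a stromal fraction
$s \in [0,1]$ from a Beta($\alpha$, $\beta$) (default Beta(2, 2)); normals
draw from a lower, tighter Beta(4, 12), reflecting the lower and less
variable stromal admixture of normal tissue. Program genes (default 50,
containing both seed genes) have log2-expression

$$x_{gj} = b_g + \lambda_g \tilde{s}_j + \varepsilon_{gj}, \qquad
\varepsilon_{gj} \sim N(0, \sigma^2),$$

where $\tilde{s}$ is the stromal fraction standardized to the tumour
samples' mean and SD. Loadings act on the *standardized* fraction — the
same scale on which the survival effect is defined — so that a unit loading
with noise SD 0.5 yields a generative between-gene correlation of
$1/(1+0.25^{\,}/1) = 0.8$, matching the "tightly co-expressed program"
regime the pipeline is designed to find. Defining loadings on the raw
fraction would cap attainable correlations at 0.5 (its variance is at most
0.25), making a strongly co-expressed program unrepresentable.

**Methylation silencing.** One gene carries a promoter methylation signal:
each sample has a latent promoter methylation level (Beta(8, 2) in tumours,
Beta(2, 8) in normals); promoter probes observe it with N(0, 0.05) probe
noise clipped to [0, 1]; non-promoter probes at the same locus are
independent Beta(2, 2). The gene's log2-expression decreases by
`meth_slope` (default -4) per unit mean promoter beta.

**Survival.** Event times are exponential with hazard
$h_j = h_0 \exp(\theta \tilde{s}_j)$ (default $h_0 = 10^{-3}$/day,
$\theta = \log 2$). Censoring is independent uniform on $[0, C]$, with $C$
solved numerically so the *expected* censored fraction equals
`censor_rate` (default 0.3) — the simplest mechanism satisfying the
non-informative censoring assumed by Kaplan-Meier and Cox.

**Scale.** Log2 values are exponentiated (`2^x - 1`, floored at 0) to an
RSEM-like right-skewed scale; baselines are drawn from Uniform(4, 10) so the
floor is essentially never active. Everything is reproducible from
`rng_seed`, which is fanned out deterministically per cohort (and, in the
pipeline, per stage) so stage results do not depend on execution order.

**What it does not emulate.** Real library-size variation, gene-length and
GC biases, batch effects, correlated background genes, non-proportional
hazards, informative censoring, copy-number effects, and per-cancer
differences in effect size. Passing recovery tests therefore demonstrates
that the estimators are correct and calibrated under the stated model, not
that they are robust to every artefact of real cohorts.

# Tunable parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `program_loading` | 1.0 | log2 expression per SD of stromal fraction |
| `noise_sd` | 0.5 | log2-scale residual SD |
| `meth_slope` | -4 | log2 expression per unit promoter beta |
| `survival_log_hr` | log 2 | log hazard per SD of program activity |
| `censor_rate` | 0.3 | expected censored fraction |
| `frac`, `reps` | 0.7, 500 | resampling subsample fraction and count |
| ssGSEA `alpha` | 0.25 | rank-weight exponent |
| consensus `r_threshold` | 0.5 (strict) | per-cancer correlation floor |
| consensus `frac_threshold` | 0.5 (inclusive) | required fraction of cancers |
| `edge_threshold` | 0.8 (strict) | designated-cohort edge floor |
| screen `min_group` | 5 | smallest dichotomized arm |

# Numerical and design choices

**Youden cutoff.** Candidate thresholds are midpoints between consecutive
distinct values. J is evaluated on the integer lattice
($a\,n_{neg} + b\,n_{pos} - n_{pos} n_{neg}$, with $a$, $b$ the
true/false-classification counts), so ties between thresholds — and between
the two test-positive orientations, which negate J exactly — are resolved
exactly rather than by floating-point noise; ties break to the smallest
threshold. The orientation is chosen so J >= 0, but the reported "high"
group is always expression-above-cutoff, so hazard ratios read as high
versus low regardless of effect direction. The binary outcome is the event
indicator irrespective of time.

**Mann-Whitney U.** U counts pairs with $x_i > y_j$ plus half-credit for
ties. The p-value is exact (full enumeration via the null distribution of
the rank sum) when the smaller sample has at most 8 observations and the
pooled data are tie-free; otherwise the normal approximation with tie and
continuity corrections is used. The boundary is deterministic and
documented rather than adaptive. Two-sided throughout; a Benjamini-Hochberg
column is reported as supplementary output but the significance flag is the
unadjusted p < 0.05.

**Cox regression** uses the Efron tie correction (Breslow available via
`ties`). Monotone partial likelihood (separation) is reported as
non-estimable instead of a huge finite hazard ratio; detection combines the
fitter's infinite-coefficient diagnostic with |beta| > 10 or a non-finite
standard error (on the per-SD log-hazard scale, |beta| = 10 is far beyond
any biologically plausible effect). Confidence intervals are Wald
(exp(beta +/- 1.96 SE)); the Wald p is primary, the log-rank p is reported
alongside; no multiplicity correction, matching the unadjusted univariate
design.

**Resampling screen.** Subsampling without replacement (70%, 500 reps),
re-deriving the cutoff per replicate so cutpoint instability is part of
what is assessed. Summaries are the median hazard ratio over estimable
replicates and the fraction concordant with the full fit (same side of 1).
Note that because each subsample shares 70% of its data with the full fit,
concordance does *not* calibrate to 0.5 under the null — it concentrates
around ~0.7 with wide per-dataset spread — so it should be read as a
stability measure for a reported association, not as a null-calibrated
test statistic.

**ssGSEA.** Ascending ranks (average ranks for ties) weighted by
$v^\alpha$ with $\alpha = 0.25$; the score is the summed gap between the
weighted in-set and uniform out-of-set cumulative distributions, with no
cross-sample normalization. When the set covers all genes the score is 0 by
convention. Rank-based scores are compositional: a coordinated program
shifts the ranks of every other gene, so a "null" signature only decouples
from the program when the program is a realistically small fraction of the
measured genome (~1%, as in a transcriptome); tests state the panel sizes
they use accordingly. Externally computed score tables can be supplied in
place of the built-in scorer for exact replication of published stromal
scores, whose exact parameterization is not reconstructable here.

**Per-sample set statistic.** Two-sample t of in-set versus background
fold changes against the mean reference sample. If both variances vanish
the statistic is 0 when the means also coincide (a sample identical to the
reference has zero enrichment for every set) and undefined otherwise. Sets
with fewer than 2 measured genes are dropped with a record. Because the
background mean contains the program genes, set statistics are relative
measures; with a compact gene panel a random set can anti-correlate with
the program, which disappears at realistic genome dilution.

**Consensus rule.** Correlation thresholds are strict (> 0.5, > 0.8) and
the cancer-fraction threshold is inclusive (>= 50%), following the rule's
wording; undefined correlations never pass; only positive correlation
qualifies. Within the single designated cohort the edge weight is the plain
Pearson r (there is nothing left to average over). Tumour-only samples are
used for all co-expression profiles. Missing values use pairwise-complete
observations with a floor of 3 pairs; constant vectors yield an undefined
(NA) correlation, never a silent 0.

**Methylation correlations** pool normal, primary and metastatic samples by
default (the per-group restriction is a flag), default method Pearson with
Spearman available. Probe-to-gene assignment comes from the methylation
table's own gene column; no external genome annotation is consulted.

# Problem sizes used by the test suite

The oracle-equivalence checks use 500 random Youden instances, full
Mann-Whitney enumeration for all group sizes up to 6, 50-gene x 6-cancer
consensus fixtures, and a 50-point grid-search comparison of the Efron
partial likelihood at step 1e-4. Recovery checks use the generator's
reference conditions: 6 cancers x 300 tumours for the consensus network,
n = 400 with 500 resampling replicates for hazard recovery, 500 simulated
fits for CI coverage, 200 simulations for methylation sign recovery, and
n = 200 for stromal-score recovery. These sizes are the package's chosen
reference conditions; enlarging them only tightens the Monte-Carlo bands.

# Known limitations

- The survival screen assumes proportional hazards and an event-indicator
  ROC label; fixed-horizon labels are not implemented.
- The ssGSEA scorer is a self-contained stromal proxy, not a reimplementation
  of any specific published scoring service; absolute score values are not
  comparable across gene panels (use the external-scores input for exact
  replication).
- The consensus rule treats each cancer equally regardless of cohort size.
- No gene-identifier aliasing: symbols are matched case-sensitively, and
  unmatched gene-set symbols are simply not measured.
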