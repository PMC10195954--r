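---
title: "Methods: a one-class neuroendocrine differentiation index and its downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a one-class neuroendocrine differentiation index and its downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nedindex)
```

## The problem

Small-cell lung cancer is the prototypical neuroendocrine (NE) lung
tumour, but NE differentiation is not binary: a fraction of non-small-cell
lung cancers (NSCLC, chiefly adenocarcinomas) express NE programs to a
varying degree, with consequences for prognosis, immune infiltration,
mutation burden and therapy response. `nedindex` quantifies that degree
per sample from bulk expression alone. The idea is to learn what NE lung
cancer "looks like" transcriptome-wide from a cell-line panel in which the
NE class is unambiguous (SCLC lines), and then score arbitrary tumours by
how much their expression profile resembles the learned signature.

## The one-class model

Let $x_i \in \mathbb{R}^p$ be the expression profile of training line $i$
(genes $\times$ 1). The signature is the minimizer of the one-class
logistic objective

$$
f(w) \;=\; \frac{1}{n}\sum_{i=1}^{n}\log\!\left(1+e^{-w^\top x_i}\right)
\;+\;\lambda_1\lVert w\rVert_1\;+\;\frac{\lambda_2}{2}\lVert w\rVert_2^2 ,
$$

i.e. intercept-free logistic regression in which every training sample is
a positive example. The elastic-net penalties keep the problem strictly
convex and the solution unique. Defaults are $\lambda_1 = 0$,
$\lambda_2 = 1$, matching the established one-class stemness-index
workflow this design follows; neither value is critical because
downstream scoring uses only the *ranks* of $w$.

Two properties of this objective shaped the implementation:

* **Centering order matters.** If the training matrix itself is centered
  gene-wise, then $\sum_i w^\top x_i = 0$ for every $w$, and by Jensen's
  inequality $w = 0$ is the global optimum — the model learns nothing.
  The correct workflow (`train_index_model()`) therefore centers the
  *full* two-class panel and only then extracts the NE columns: relative
  to the panel mean, NE lines carry a positive offset on their signature
  genes, and it is exactly that offset the weights pick up.
* **The ridge solution lives in the span of the training profiles.**
  With $\lambda_1 = 0$ the stationarity condition gives
  $w = X a / (n\lambda_2)$ for some $a \in \mathbb{R}^n$, so the fit runs
  as a damped Newton iteration in the $n$-dimensional sample space
  ($n \le 185$ here) regardless of the gene count. This makes training
  exact (smooth-part gradient `0` at the solution), deterministic
  (cold start at $w = 0$, no randomness), and fast. With
  $\lambda_1 > 0$ a monotone proximal-gradient iteration with a
  Lipschitz step ($L = \lambda_2 + \sigma_{\max}(X)^2/4n$) is used
  instead. Both paths terminate when the relative objective change drops
  below `tol` ($10^{-6}$ by default, `max_iter` 1000) and both produce a
  non-increasing objective trace.

`log(1+e^{-s})` is evaluated through the overflow-safe softplus identity.

## From weights to the index

A new sample is scored by the Spearman correlation (average-rank ties)
between $w$ and the sample's expression over the genes the two share
(`score_samples()`); the number of shared genes is recorded. Raw
correlations are mapped to the NED index by the cohort-relative linear
transform $(\rho - \rho_{\min})/(\rho_{\max} - \rho_{\min})$
(`normalize_index()`), read as "(x − min)/(max − min)" consistently with
the microarray harmonization formula. Two consequences are documented
prominently:

* the index is **cohort-relative** — 0 and 1 are the observed extremes of
  the cohort at hand, so indices are not comparable across cohorts; and
* scoring is **rank-based** — any strictly monotone transform of a
  sample's expression (log, exp, scaling) leaves its score bitwise
  unchanged, which is why RNA-seq `log2(TPM+1)` and min-max-scaled
  microarray profiles can both be scored against the same weights.

Cohorts are split at the median index (`stratify_median()`); a sample
sitting exactly on the median goes to the *low* stratum (strict `>` for
high), a deterministic tie rule that matters for odd cohort sizes.

## Input harmonization

RNA-seq abundances enter as TPM and are transformed to `log2(TPM+1)`
(`log2_tpm()`). Microarray intensities, already log-scale, are min-max
scaled to $[0,1]$ **per gene** (`minmax_01()`): the per-feature reading
of the formula, which makes gene ranks comparable across samples; the
choice is stamped into the output metadata. Constant gene rows scale to 0
with a warning rather than an error. Cross-cohort work first restricts
all matrices to their sorted common gene set (`intersect_genes()`).
Duplicate gene symbols are collapsed by keeping the highest-mean row;
missing values fail loudly unless gene-wise median imputation is
requested. Gene identifiers are case-sensitive symbols with no alias
mapping.

## Enrichment scores

`ssgsea()` implements the single-sample enrichment walk: per sample,
genes are ranked by expression (ties averaged) and walked in descending
order; set genes advance the running statistic in proportion to
$\nu^\alpha$ (ascending rank $\nu$, exponent $\alpha = 0.25$ by default)
and non-set genes retreat it uniformly; the enrichment score is the *sum*
of the walk. Scores are cohort-normalized by the global range by default.
One subtlety: for a random gene set the rank-weighted walk has a small
*positive* expected value whenever $\alpha > 0$ (early, highly-ranked
hits are up-weighted), so the "random sets score zero on average"
property is exact only for the unweighted walk ($\alpha = 0$); the test
suite checks it there.

ESTIMATE-style output (`estimate_scores()`) is the pair of ssGSEA scores
of a stromal and an immune signature set plus their sum. `gsea_preranked()`
is the classic weighted Kolmogorov–Smirnov running sum (weight exponent
1, signed extremum). Because a preranked analysis has no phenotype labels
to permute, the null is built by resampling random gene sets of equal
size; NES divides the ES by the mean same-sign null magnitude, and
p-values are BH-adjusted across sets. Differential expression between
index strata is a vectorized Welch $t$ per gene with BH FDR; the top-150
up/down gene lists by $t$ (`top_k_export()`) are the export consumed by
connectivity-map style compound queries.

## Mutation landscape

`tmb()` divides a sample's variant-record count by 38 Mb of exome; all
record classes count by default with a flag to drop silent variants
(which of the two the original workflow used is not stated, so both are
provided). Single-nucleotide substitutions collapse to the six
pyrimidine-reference classes via reverse complementation; C>T and T>C are
transitions, the rest transversions, and per-sample Ti + Tv fractions sum
to one. Differential mutation between strata is a per-gene 2×2 Fisher
exact test flagged at unadjusted $p < 0.05$ (the screening rule used in
the field; BH is available behind a flag). Pairwise co-occurrence /
exclusivity over the top-25 most frequently mutated genes is the standard
somatic-interaction computation: Fisher on joint mutation status, labelled
by whether the cross-product odds ratio exceeds 1. An exact multi-gene
exclusivity test is deliberately out of scope; pairwise Fisher stands in.
Reported odds ratios are cross-product ratios with 0.5 added to every
cell only when a zero cell occurs; p-values come from the conditional
hypergeometric distribution.

## Survival machinery

Kaplan–Meier estimation, the log-rank test and all Cox fits (Efron tie
handling) are delegated to the `survival` package; the risk-signature
pipeline (`screen_and_fit()`) chains

1. a raw median-absolute-deviation filter (no 1.4826 consistency
   constant, the common expression-filter convention) at `mad_min = 0.5`;
2. optionally, the top-$K$ genes by absolute Spearman correlation with a
   per-sample index ($K = 774$ by default) — a deliberately simple
   stand-in for co-expression module selection, which is out of scope;
3. a univariate Cox screen at $p < 0.05$; and
4. an L1-penalized Cox fit with 10-fold cross-validation
   (`glmnet`), taking $\lambda$ at minimum partial-likelihood deviance
   under a fixed fold seed.

The risk score is the exact linear predictor
$\sum_g \text{expression}_g \times \text{coefficient}_g$. Discrimination
is evaluated with Harrell's concordance (pairs usable iff the shorter
follow-up ended in an event; half credit for risk ties; an optional
horizon truncates pairs for a time-dependent variant) and with the
IPCW cumulative/dynamic AUC at a horizon $t$ (cases weighted by
$1/\hat G(T^-)$, controls by $1/\hat G(t)$, $\hat G$ the Kaplan–Meier
estimate of the censoring distribution); without censoring the latter
reduces exactly to empirical pair counting. The optimal cut-point scan
maximizes the log-rank statistic over observed marker values inside the
10–90% quantile window, ties resolving to the lower threshold.
`scale_free_fit()` evaluates candidate soft-threshold powers by the
$R^2$ of the log-log fit of the 10-bin connectivity histogram and picks
the smallest power reaching 0.9.

## What the synthetic cohorts emulate

`sim_config()` fixes the study conditions; the defaults are a 50/135
NE/non-NE cell-line panel, 2 000 genes, and 300 bulk tumours:

| parameter | default | meaning |
|---|---|---|
| `signature_effect` | 2 (log2) | NE shift of the 100 signature genes; canonical NE markers separate SCLC from NSCLC by well over 4-fold |
| `noise_sd` | 0.5 | residual log2 noise around gene baselines drawn from U(2, 8) |
| `ne_frac_a`, `ne_frac_b` | 2, 2 | Beta law of the latent per-tumour NE fraction $f$ |
| `hazard_coef_ne` | −1 | log-hazard per unit $f$: high NE differentiation confers *better* prognosis |
| `baseline_hazard` | 1/500 per day | exponential baseline |
| `censor_rate` | 0.3 | expected censored fraction |
| `tmb_base`, `tmb_ne_slope` | 100, 200 | Poisson mutation-count mean $= 100 + 200f$ |
| `prognostic_coefs` | ±0.7 ×5 | log-hazard effects of 5 planted genes carrying an extra unit-variance component |

Bulk profiles are convex mixtures $f \cdot \mu_{NE} + (1-f)\cdot
\mu_{nonNE}$ of the two *mean* profiles plus Gaussian noise — mixing at
the mean level, not single-cell sampling, which is sufficient for a
rank-based score. A 100-gene immune compartment is expressed in the
non-NE mean profile, so immune enrichment falls as $f$ rises, mirroring
the immune-cold phenotype of NE-high tumours. Censoring is per-sample
Bernoulli(`censor_rate`) with the censored observation drawn uniformly on
$(0, T)$, which makes the realized event rate match $1-$`censor_rate`
exactly in expectation. Planted differential-mutation genes are excluded
from the background mutation pool so the planted group contrast is the
only mechanism acting on them. `simulate_scale_free()` builds
co-expression fixtures from an exactly orthonormal basis with stratified
power-law loadings, so the sample correlation matrix — and hence the
connectivity distribution at every soft-threshold power — is exact by
construction.

What passing tests on these cohorts do **not** show: robustness to
platform/batch effects, to compositional mixtures of more than two cell
states, to non-proportional hazards, or to mutation-calling artefacts —
none of which the generator emulates. The generator's value is known
ground truth (latent $f$, planted gene lists, true hazards) for recovery
and null-calibration tests, not realism of marginal distributions.

## Problem sizes and determinism

All simulations are sized to run the full suite in well under a minute of
CPU: default cohorts of 2 000 genes × 300 tumours for end-to-end
recovery, 500 genes for risk-signature recovery (with 10 permutation
replicates for the null), 200-replicate null calibrations, and reduced
(400-gene) cohorts for plumbing tests. Every stochastic path takes an
explicit seed; the command-line driver fans one global seed out to fixed
per-stage offsets and writes manifests free of timestamps and absolute
paths, so identical configs reproduce byte-identical artifacts.

## Known limitations

* The index is cohort-relative by construction; comparing absolute index
  values across cohorts requires a shared anchor the method does not
  provide (and the original workflow did not perform).
* Whether scored cohorts should themselves be gene-centered first is
  ambiguous in the source procedure. Per-gene centering subtracts a
  different constant from each gene and therefore *does* reshuffle the
  cross-gene ranks within a sample, so the choice is not neutral. This
  implementation scores raw normalized profiles — the simpler reading —
  and documents the ambiguity here.
* Pairwise Fisher interactions do not capture higher-order exclusivity.
* The co-expression pre-filter stage is a rank-correlation screen, not
  module detection; gene sets selected this way lack the topological
  guarantees of a full network analysis.
* `fisher_exact_2x2` reports the cross-product odds ratio, which differs
  from the conditional maximum-likelihood estimate for extreme tables
  (the p-value is exact either way).
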