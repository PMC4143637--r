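---
title: "Dynamic pathway analysis of longitudinal blood pressure: models and methods"
author: "dynpath authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic pathway analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynpath)
```

# Scope

`dynpath` analyzes a longitudinal quantitative trait — systolic blood
pressure (SBP) measured at three exams, plus an independent null trait —
against sequence variants of unrelated individuals, in three stages:
gene-level association with a hierarchical grouped-effect regression,
rank-based pathway enrichment per exam, and pathway-crosstalk networks
between adjacent exams. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, what the synthetic
data generator does and does not emulate, and the known limitations.

# Treatment adjustment

Antihypertensive treatment lowers observed SBP and is given preferentially
to high-SBP individuals, confounding genotype–SBP association downward. The
standard correction adds a constant back to treated person-exams before
analysis; the default is 10 mm Hg, applied once per exam
(`adjust_treatment()`, `prepare_traits()`). The null trait is never
adjusted. The adjustment is deliberately not idempotent — applying it twice
shifts treated entries by 20 mm Hg — so the pipeline applies it in exactly
one place.

# The hierarchical grouped-effect model

## Form

For a gene whose variants are partitioned into groups $G_k$ (rare/common in
stratified mode, $K \le 2$; all variants in combined mode, $K = 1$), the
linear predictor is

$$\eta_i = \beta_0 + \sum_{k} g_k \sum_{j \in G_k} \beta_j z_{ij},$$

with minor-allele dosages $z_{ij}$, a Gaussian identity-link likelihood with
dispersion $\theta$, and priors

$$\beta_j \sim N(1, \tau_\beta^2), \qquad g_k \sim N(0, \tau_g^2).$$

Centering the variant coefficients at 1 makes $g_k$ interpretable as the
group-average per-allele effect (mm Hg per allele) and identifies the
$g_k \beta_j$ product: the scale freedom $(g_k, \beta) \mapsto
(c\,g_k, \beta/c)$ is broken by the prior center. With all $\beta_j$ frozen
at 1 (`beta_update = FALSE`) the model collapses exactly to a burden
regression on per-group minor-allele counts. The gene-level test is the Wald
test of $g_k = 0$.

Defaults: $\tau_\beta = 0.5$ — coefficients may plausibly halve or double
relative to the group average, but not flip sign wildly; $\tau_g = 10$ —
weak on the mm Hg scale. Both are exposed in `hier_control()`.

## Fitting: blockwise EM with penalized least-squares steps

The fitter alternates three closed-form steps:

1. **Group-effect step** — regress the trait on the $K$ collapsed scores
   $s_{ik} = \sum_{j \in G_k} \beta_j z_{ij}$ plus intercept, with the $g$
   prior as a ridge penalty.
2. **Coefficient step** — given $g$, update $\beta$ by ridge regression
   centered at 1. Algebraically this is the posterior mean of $\beta$ under
   its prior.
3. **Dispersion step** — $\theta$ from the (expected) residual sum of
   squares.

Two variants of this scheme are provided, and the distinction matters:

* `method = "em"` (default) treats the variant coefficients as *latent*:
  the posterior covariance of $\beta$ from step 2 enters the cross-products
  of step 1, the dispersion update, and the standard errors. The scheme is
  then the exact EM (more precisely ECM) algorithm for the marginal model
  $y \sim N(\beta_0 + W\mathbf{1},\; \theta I + \tau_\beta^2 W W^\top)$,
  $W = Z\,\mathrm{diag}(g_{k(j)})$, and the penalized marginal
  log-likelihood increases monotonically (asserted at every iteration under
  `debug = TRUE`). Wald standard errors for $g$ come from the observed
  information (numerical Hessian) of the penalized marginal log-likelihood
  in $(\beta_0, g, \log\theta)$. At the null the marginal model loses its
  variance term and the test reduces to a burden regression, which is why
  this method is calibrated-to-slightly-conservative under the null — the
  property the null-trait analyses rely on.
* `method = "plugin"` is the literal blockwise scheme: every step and the
  standard errors condition on the current fitted coefficients. Because
  those coefficients are themselves adapted to the trait, the plug-in Wald
  test is **anti-conservative**, increasingly so for groups with many
  and/or high-variance variants. In Monte Carlo at $n = 142$ with 20
  variants per gene, plug-in rejection at $|z| > 1.96$ runs at 12–16%
  against the nominal 5%, while the EM method stays at or below nominal.
  This is precisely the mechanism by which a combined analysis of all
  variants in a gene (one group, many common variants) shows grossly
  inflated false-positive rates relative to the rare/common-stratified
  analysis, and the package keeps the plug-in method so that this failure
  mode can be studied; the acceptance suite demonstrates the inequality.

Initialization is the burden special case ($\beta_j = 1$, $g_k = 0$,
$\beta_0 = \bar y$); convergence is declared when the largest absolute
parameter change falls below `tol` ($10^{-6}$ by default) within `max_iter`
(200) iterations. Non-convergence is a flagged result with a warning, never
an exception, so genome-wide scans cannot abort on a single ill-conditioned
gene. The fit is deterministic given the data and control settings.

Numerical notes. The dispersion is floored at $10^{-12}$ to keep the
objective finite on degenerate (perfectly fitted) data. With *diffuse*
priors the marginal likelihood is scale-degenerate — $g$ and $\tau_\beta$
enter only through their product — so the classical diffuse-limit identities
(single-variant fit recovering the OLS slope; full-rank fits recovering the
OLS fitted values) hold for the plug-in scheme and are asserted there; the
EM default relies on proper priors to pin the scale. If the Hessian of the
marginal likelihood is numerically singular, standard errors fall back to
the covariance-corrected information of the group-effect step.

## Choice of standard errors

Conditional (plug-in) Wald summaries are what a naive reading of the
blockwise algorithm produces, but they ignore that the collapsed scores were
trained on the trait; their null distribution is visibly too wide, and at
the far tail (the region that matters after multiplicity correction over
hundreds of genes) the excess reaches an order of magnitude. The marginal
observed-information standard errors showed zero excess beyond the
$2.5\times10^{-4}$ tail in $6{,}000$ null fits. Conservatism, not
anti-conservatism, is the acceptable direction for a screening tool, so the
marginal version is the default and the conditional one is opt-in.

# Gene scan, multiplicity, and calling

`scan_genes()` fits one model per gene × trait (T1–T3 adjusted SBP, Q1) in
the requested mode and BH-adjusts p values **within each (trait, mode,
group) family** — rare and common p values are never pooled, which is the
family definition under which per-trait, per-group gene counts are
coherent. Genes with no polymorphic variants in the analyzed individuals
are skipped (logged); non-converged fits are retained flagged, because
dropping them would shrink the FDR family. A gene is *called* when its
adjusted p value is strictly below the FDR level (default 0.05).

# Pathway enrichment

The gene-level statistic is the rare-group Wald $z$ (configurable to the
combined-mode $z$). Pathways are filtered to those with at least 5 genes
among the ranked genes; genes without a statistic (no rare variants) leave
the universe, while genes on no pathway remain as background. The test is a
two-sample rank-sum comparison of in-set versus out-of-set statistics:
mid-ranks for ties, tie-corrected variance, continuity correction, and
exhaustive enumeration instead of the normal approximation when the
universe has at most 10 genes. Although gene-set rankings of this kind are
often described loosely as signed-rank procedures, what is actually
computed — here and in the standard implementations — is the two-sample
rank-sum comparison; the implementation agrees with `limma::wilcoxGST` to
machine precision on continuous rankings.

The default alternative is `"mixed"` (rank $|z|$): group-effect signs
depend on arbitrary allele orientation across genes, so two-sided evidence
is the safe default; `greater`, `less` and `two.sided` on signed $z$ are
available. Nominal enrichment is $p < 0.05$; at these sample sizes
FDR-significant pathways are not expected, matching the reference analyses.

# Crosstalk networks

For an adjacent exam pair $(t, t+1)$: nodes are pathways nominally enriched
at either exam; an undirected edge joins two distinct pathways when one is
enriched at $t$, the other at $t+1$ (either orientation) *and* their member
sets share at least one functional gene — sharing non-functional genes is
not crosstalk, which keeps every edge biologically anchored. Edges carry
the shared functional genes and a flag marking pairs enriched at both
exams; a pathway enriched at both exams is a persistent node, not a
self-loop. The truth set provides "functional" in simulation; on real data
a caller may substitute BH-significant genes, which is flagged in the
documentation as a fallback, not reference behavior. Networks export to
GraphML (all attributes) and SIF (topology), both loadable in Cytoscape.

# Evaluation

Calls are scored against the designated functional genes: positives at
adjusted $p <$ FDR, FPR $= 100\cdot$FP/(FP+TN), FNR $= 100\cdot$FN/(FN+TP).
Functional genes never tested (monomorphic in the analyzed individuals) are
excluded from denominators — they are undetectable in the data, and
counting them as misses would report a bias of the cohort as a bias of the
method. ROC curves sweep the unadjusted p values (BH is monotone, so AUC is
unchanged); the trapezoid AUC equals the Mann–Whitney pairwise probability
with half-credit for ties, and is invariant to monotone transforms of p.

# The synthetic study generator

`simulate_study()` emulates the statistical structure the analysis assumes:

* **Genotypes** — 142 unrelated individuals by default; 200 genes laid out
  on one synthetic chromosome (20 kb bodies, 50 kb spacing so 10 kb flanks
  do not overlap); per-gene variant counts Poisson(20) truncated at 1; 70%
  of variants rare (population MAF in [0.002, 0.01)) and 30% common
  ([0.01, 0.5]), a rare-skewed spectrum typical of sequencing data;
  dosages Binomial(2, p) under Hardy–Weinberg. Optional within-gene linkage
  disequilibrium via a Gaussian-copula factor (`ld_r`) preserves the
  marginal frequencies; the default is independence.
* **Truth set** — 31 functional genes by default; one functional variant
  each, preferentially rare and polymorphic in the sample; per-allele
  effects derived from a configured variance-explained fraction via the
  additive identity $b = \sqrt{v\sigma_y^2 / (2\,\mathrm{maf}(1 -
  \mathrm{maf}))}$. The default $v = 0.00273$ per functional variant
  reflects how small realistic single-variant contributions are — at
  $n = 142$ they are essentially undetectable, which is the honest
  operating point; power studies raise $v$ explicitly.
* **Longitudinal SBP** — true SBP = 120 mm Hg baseline + per-exam drift
  (0/4/8 mm Hg, blood pressure rising with age) + individual random
  intercept + genetic contribution + exam noise; total SD 15 mm Hg with
  within-individual correlation 0.6 split between intercept and noise (the
  simplest structure producing positive cross-exam correlation).
* **Treatment** — assigned to the highest-true-SBP individuals up to
  prevalences 15.5%, 35.9%, 51.4% (22, 51, 73 of 142) and sticky across
  exams, because antihypertensive treatment targets high blood pressure and
  is rarely withdrawn; observed SBP is true SBP − 10 mm Hg when treated.
* **Null trait Q1** — standard normal on a dedicated random stream, so it
  is independent of genotypes and SBP *by construction*.
* **Pathways** — random gene sets (default 50 sets, sizes 5–20) with a
  configurable number forced to contain at least one functional gene, so
  enrichment and crosstalk are exercisable.

Everything is reproducible byte-for-byte from the single configured seed;
each generator operation draws from its own derived stream.

What the generator does **not** emulate: family structure or relatedness,
realistic LD maps (the copula factor is exchangeable within a gene, not a
recombination map), cross-gene LD, sex/age covariates, genotyping error or
missingness, and time-varying genetic effects. Consequently, passing tests
demonstrate the statistical behavior of the methods under clean
Hardy–Weinberg sampling — calibration of the null, recovery of planted
effects, the stratified-versus-combined inflation contrast — not robustness
to the full pathology of real cohorts. In particular, real-data inflation
driven by long-range LD can exceed what the plug-in mechanism reproduces at
desk scale.

# Design choices where the design was open

* **Priors** — families and scales are not canonical; Normal priors with
  $\beta$ centered at 1 were chosen for interpretability and closed-form
  steps. MCMC was rejected in favor of deterministic EM: a genome scan
  needs thousands of fits whose results do not wobble across runs.
* **Standard errors** — marginal observed information by default (see
  above); plug-in conditioning retained as an explicit, documented method.
* **Adjustment families** — BH within (trait, mode, group); pooling across
  groups would let a powerful rare-variant family buy calls for the common
  family and vice versa.
* **Variants in overlapping gene windows** are analyzed in every gene they
  map to; with 10 kb flanks this is the common convention and keeps gene
  results self-contained.
* **Missing genotypes** are mean-imputed per variant (keeps the design
  dense and the MAF unchanged); multi-allelic records are rejected rather
  than silently split.
* **MAF is always recomputed on the analyzed individuals**, never taken
  from annotation: the rare/common boundary at 1% refers to the cohort
  being analyzed.
* **Coordinates** are 1-based inclusive everywhere (VCF convention); the
  gene-model file declares this in its header to avoid the 0-based BED
  trap.
* **Desk-scale problem sizes** — the test and acceptance suites use 20
  replicate studies of 200 genes × ~20 variants for null calibration, 100
  replicates at $n = 1000$ for effect recovery, and 25 replicates of 120
  variant-rich genes for the inflation contrast; chosen to make Monte-Carlo
  assertions sharp while keeping a full run in minutes on one CPU.
* **Inflation contrast at the nominal level** — at these problem sizes the
  BH-level false-positive rates of both strategies on a null trait are
  ~0, so the stratified-versus-combined inequality is asserted for the
  plug-in method with positives at unadjusted $p < 0.05$, where it is
  identifiable; the BH-level definition is used everywhere else.

# Known limitations

Gaussian traits only (no binomial family, no covariates beyond the
intercept and the treatment adjustment); Wald inference rather than
likelihood-ratio or permutation; conditional-versus-joint uncertainty in
the variant coefficients is handled by the marginal information, not by a
fully Bayesian posterior; enrichment is the streamlined rank test, not the
weighted Kolmogorov–Smirnov statistic of genome-wide GSEA; crosstalk edges
carry no significance assessment. The evaluation's FNR depends on which
functional genes are polymorphic in the analyzed cohort — with 142
individuals many are not, and the reported FNR reflects that restriction.
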