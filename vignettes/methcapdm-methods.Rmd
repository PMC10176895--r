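---
title: "Models and methods in methcapdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in methcapdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcapdm)
```

methcapdm analyses two-group cord-blood methylomes measured by targeted
bisulfite (methyl-capture) sequencing. This vignette records the statistical
models, the tunable parameters and their defaults, the numerical decisions,
and what the bundled synthetic-cohort generator does and does not emulate.
It states no empirical result beyond what the package's tests and acceptance
script themselves compute.

## Data model and filtering funnel

The central object is a `MethylomeMatrix`: per CpG site and sample, a
methylated count $m$ and a total count $t$, with missing cells stored as `NA`
in both matrices and the beta value defined as $\beta = m/t \in [0,1]$.
Positions are 1-based coordinates of the C of the CpG dinucleotide on the
forward strand; counts are assumed pre-merged across strands. BED input and
output use 0-based half-open intervals, and the conversion happens only at
I/O boundaries — internally everything is 1-based closed, the convention of
the GenomicRanges stack used for all interval work.

Filtering proceeds in a fixed order: (1) drop sites overlapping any
exclusion interval (SNPs, blacklisted regions); (2) mask every cell with
coverage outside `[min_cov, max_cov]` (defaults 15 and 500, both inclusive);
(3) drop sites with fewer than `min_samples` (default 30) non-missing cells —
counted *after* the coverage mask, which is the reading of the retention rule
adopted here; (4) drop chrX/chrY. The operation is idempotent and monotone
in its thresholds, which the test suite asserts on random matrices.

## Cell-type deconvolution

Bulk cord blood mixes seven cell types (B, CD4+ T, CD8+ T, granulocytes,
monocytes, NK, nucleated red blood cells). Given a reference panel $X$ of
marker-CpG methylation fractions (CpGs × cell types), each sample's marker
betas $y$ are projected by nonnegative least squares,
$\min_{w \ge 0} \lVert y - Xw \rVert_2$ (Lawson–Hanson, via
`pracma::lsqnonneg`). Two deliberate choices:

* **No sum-to-one constraint.** The raw nonnegative projections are used as
  covariates, matching the behaviour of the projection method this
  reimplements; a `normalize` flag rescales for reporting only.
* **Coverage and imputation.** Only marker CpGs non-missing in at least
  `min_frac` (default 0.9) of samples enter the projection; remaining missing
  betas are imputed with the mean of the other samples at that CpG, and CpGs
  missing everywhere are dropped first.

Tests assert the Karush–Kuhn–Tucker conditions of every solution at
tolerance 1e-8, exact recovery (1e-10) of noiseless mixtures, and ≤0.05
per-sample RMSE against simulator truth at 60× coverage.

## Per-CpG binomial regression and q-values

At each site the model is a binomial logistic regression of $(m, t-m)$ on an
intercept, the group contrast, and the requested covariates (infant sex,
the seven cell proportions, pregnancy complications), fitted by IRLS
(`stats::glm.fit`, 50 iterations, deviance tolerance 1e-8) on non-missing
samples. The reported test is the Wald $z$ of the contrast coefficient, the
convention of standard GLM summaries. Sites that fail to converge, sit on the
boundary (complete separation), or lack data are flagged and **excluded from
the q-value input** rather than assigned $p = 1$; this keeps the p-value set
of tested sites uniform under the null. Counts of such sites are reported.
If the design matrix including all seven proportion columns is numerically
rank-deficient (condition number above 1e10), the last proportion column is
dropped with a warning — the minimal intervention.

False discovery control uses Storey q-values: with $p_{(1)} \le \dots \le
p_{(m)}$, $q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j$. The null
proportion $\hat\pi_0$ is estimated on the grid $\lambda = 0.05, 0.10,
\dots, 0.95$ by a cubic smoothing spline through
$\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$ evaluated at
$\lambda = 0.95$ and clamped to $(0, 1]$; for fewer than 100 p-values the
smoother is unreliable and $\pi_0 = 1$ is used. With `pi0_mode =
"fixed_one"` the q-values coincide *exactly* with Benjamini–Hochberg
adjusted p-values, an identity the tests assert on a thousand random
vectors. DMCs are records with $q < 0.05$ (configurable), annotated with the
group beta difference (case − control means over non-missing samples per
group), its direction (hyper/hypo), and the <10% / 10–20% / >20% magnitude
bins used in reporting.

## Region merging and annotation

Same-direction DMCs chain left-to-right per chromosome while the positional
difference between consecutive members is **≤ 250 bp (inclusive)** — the
natural reading of "within 250 bp", fixed here so results are bit-for-bit
reproducible. Chains of length ≥2 become DMRs; singletons are tabulated
separately, and size statistics are reported both with and without them.
Region size is `end − start + 2`, spanning the trailing CpG dinucleotide.
Hypo- and hypermethylated chains never merge, irrespective of interleaving.

Annotation assigns each site one category per family (genic context, CpG
context, repeats) by user-declared precedence with an explicit fallback
(e.g. intergenic, open sea), so per-family count tables always sum to the
number of sites; multi-assignment, as some annotators allow, is deliberately
not supported. Enrichment of a category in a foreground set against a
background uses the Yates-corrected chi-square on the 2×2 in/out table.

## Outlier detection on PC1 gaps

Samples are scored by PCA on complete-case betas (sites covered in every
sample), each component oriented so the sample with the largest absolute
score is positive. Scores are sorted, the $n-1$ neighbour gaps computed, and
an "at most one change" (AMOC) mean-shift test applied to the gap sequence.
When the best split clears the penalty, the gap bordering the elevated
segment separates the outliers: the samples strictly beyond it on the side
with fewer samples. If that separator is interior (both sides ≥ n/2) no
outliers are declared — an "outlier set" is by definition small. The
declared set is invariant to the arbitrary sign of PC1.

The cost function required a genuine design decision. The textbook AMOC
recipe — pooled-variance Gaussian likelihood ratio
$m \log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ against an MBIC-style $3\ln m$
penalty — is useless on spacing data: gaps of sorted Gaussian scores are
strongly U-shaped (extreme-order-statistic spacings widen in the tails), so
a single-mean-shift model "finds" a changepoint in nearly every perfectly
homogeneous cohort, and its statistic barely separates real outliers from
that null. The default method therefore scores splits by the reduction in
squared error divided by a robust gap-scale estimate (squared MAD) and
compares against a **Monte-Carlo penalty calibrated to the spacings of $n$
sorted Gaussian scores** (200 internally seeded replicates, level
`alpha = 0.02`). The 2% false-alarm budget is deliberately conservative —
about one declared outlier set per fifty homogeneous cohorts — and costs no
power: a sample shifted by ten within-cluster standard deviations produces a
statistic far above even the 99.9% null quantile. The literal
likelihood-ratio recipe remains available as `method = "lr"` for comparison.

One caveat the worked examples make visible: PC1 captures the *largest*
variance structure, whatever it is. In a cohort with a strong planted group
effect and no outliers, the detector can legitimately report the smaller
group as the "separated set". On real data the procedure is meaningful
precisely because group effects on the methylome are subtle relative to a
global outlier shift.

Fisher exact tests of detected outliers against group or sex report
enrichment; zero detected outliers degenerates to $p = 1$, flagged.

## Imprinting control regions

Within each ICR interval, methylation is summarized **per CpG**: the mean
beta over non-missing samples in each group × sex cell. This averaging rule
makes CpGs — not samples — the replicates of the subsequent two-way ANOVA
(group, sex, interaction), a deliberate reading of the averaging convention
it mirrors; the alternative (samples as replicates) is noted but not
implemented. Sums of squares are Type II via `car::Anova`, which reduces to
the standard balanced decomposition when no cell is missing (asserted
against a hand-computed oracle); within-sex group contrasts use the residual
mean square with a Bonferroni factor of 2. Direction tallies average the
per-CpG differences per ICR (combined and per sex) and count hypo- vs
hypermethylated ICRs among those *with data*; capture-coverage accounting
reports the fraction of each ICR's total CpGs present in any two site sets.

## Cohort statistics

2×2 Fisher tests use the two-sided "probability at most that of the observed
table" convention; r×c tables use the Freeman–Halton extension with exact
enumeration when feasible and a seeded Monte-Carlo estimate (with standard
error) otherwise. Chi-square tests optionally apply Yates' correction (2×2
only). Unpaired t tests are computed from (mean, SD, n) summaries — pooled
variance by default, Welch optional — so demographic tables can be
recomputed from printed values; recomputation from rounded inputs can
legitimately disagree with some printed p-values, and the package reports
its recomputed value rather than silently matching. `cohort_table()` picks
the exact test when any expected cell count is below 5, the chi-square
otherwise, and records the choice per row.

## The synthetic cohort generator

The generator is the package's ground-truth instrument; its defaults *are*
the study conditions it emulates:

* two groups of 36 and 37 samples, both sexes at a 0.5 ratio, a 17:20 split
  of the case group into less/more invasive conception subgroups, and a 0.3
  complication rate;
* seven cell types with a granulocyte-dominant Dirichlet mixture law and a
  reference panel of 50 marker CpGs per cell type separated from all other
  types by ≥0.5 methylation;
* coverage drawn from a discretized log-normal (meanlog `log(80)`, sdlog
  0.55) clipped to [1, 600], so both tails of the 15×/500× filter are
  exercised while roughly a third to a half of filtered sites remain
  complete-case at n = 73 — matching the regime in which PCA outlier
  detection on fully covered sites is meaningful;
* completely-at-random missingness at rate 0.01;
* beta-binomial counts with intra-class correlation `dispersion_rho`. Real
  bisulfite data are overdispersed but no estimate is available to calibrate
  against, so the default 0.01 is a documented free parameter; `rho = 0`
  recovers the binomial analysis model exactly and is what the calibration
  checks use;
* planted effects act on the **logit scale** (so betas stay in (0,1) for any
  effect size) with scopes `both`, `male_only`, `female_only`, and
  `opposite` (+δ in case males, −δ in case females); planted sites receive
  mid-range baselines (Beta(6,6)) so a configured logit effect maps to an
  appreciable beta difference;
* imprinted blocks sit at baseline 0.5 with small logit-scale group × sex
  shifts (defaults: one female-only, one shared, one opposite-direction);
* outlier samples receive a global logit shift (default −2) at a random half
  of all sites, at most 10% of the cohort.

With all effects zero the group labels never enter the generative process,
so any downstream statistic is exchangeable under label permutation — the
type-I-error and FDR checks rest on this. The generator does **not** emulate
batch or plate effects, informative missingness, co-methylation (sites are
independent given their baselines), SNP contamination, or read-level
artefacts; passing recovery tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to those phenomena.

## Calibration, problem sizes, and known limitations

The test suite and the acceptance script size their simulations as follows:
null calibration on 20,000 CpGs × 73 samples with `rho = 0` (where the
p < 0.05 fraction must sit in 0.05 ± 0.01 and q < 0.05 yields no calls);
effect recovery on 4,000 CpGs with 500 planted ±1-logit effects at 30×
coverage (≥80% sensitivity, ≥95% sign concordance required; both reach 100%
in the seeded runs); deconvolution on 6,000 CpGs at 60×; detector operating
characteristics over 100 planted and 200 null score vectors; and merging
versus a brute-force oracle over 1,000 random DMC layouts.

Known limitations, stated plainly:

* Under overdispersion (`rho > 0`) the binomial GLM is anticonservative —
  the worked example in the README shows small-difference false calls at
  `rho = 0.01`. This mirrors the analysis model being reimplemented; a
  beta-binomial or shrinkage-dispersion test is out of scope by design.
* The q-value smoother needs a reasonably dense p-value grid; below 100
  tested sites it falls back to $\pi_0 = 1$ (Benjamini–Hochberg).
* The AMOC detector considers a single changepoint only; two outlier groups
  at opposite PC1 ends, or outlier structure beyond PC1, are out of scope.
* ICR inference treats CpGs as replicates; CpGs within an ICR are correlated
  in real data, so those p-values are descriptive rather than strictly valid
  under independence.
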