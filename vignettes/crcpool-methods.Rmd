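---
title: "Methods: pooled multi-cohort analysis of CRC stool metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled multi-cohort analysis of CRC stool metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcpool)
```

## Scope and rationale

`crcpool` implements a cross-cohort computational framework for pooled
case-control analysis of colorectal cancer (CRC) stool metagenomes. Its
starting point is the table output of taxonomic profilers (species-level
genome bins, SGBs, by samples, relative abundances in [0, 1]) and, for the
strain-level component, marker-gene multiple sequence alignments. Raw-read
processing and profiling are deliberately upstream of this package.

The central design commitment is that cohorts are never merged into one
batch-corrected table. Batch effects between sequencing studies are large,
incompletely characterized and have no consensus correction in microbiome
data, so every inferential step here is *per cohort first, pooled second*:
effect sizes are estimated within each cohort and combined by random-effects
meta-analysis; community-level tests permute labels only within cohorts;
classifiers are evaluated across cohort boundaries rather than on pooled
folds.

## The effect-size model

For a feature with relative abundance $p$, all effect-size work operates on
the variance-stabilized scale $y = \arcsin\sqrt{p}$. Within cohort $i$,
the standardized mean difference between classes is Hedges' $g$:

$$d_i = \frac{\bar y_{1i} - \bar y_{2i}}{s_{p,i}}, \qquad
  J = 1 - \frac{3}{4\,\nu - 1}, \qquad g_i = J\,d_i,$$

with $\nu = n_{1i} + n_{2i} - 2$, pooled standard deviation $s_{p,i}$, and
sampling variance
$\widehat{\mathrm{Var}}(g_i) = J^2\!\left(\tfrac{n_{1i}+n_{2i}}{n_{1i} n_{2i}}
+ \tfrac{d_i^2}{2\nu}\right)$.
The correction factor uses the common approximation $1 - 3/(4\nu - 1)$; the
exact gamma-function form differs by under 0.1% at $n \ge 10$ and was not
worth the extra surface. Positive $g$ always means "higher in class 1"
(CRC, late stage, right-sided — whichever the contrast declares first).

Cohort effects are pooled under the random-effects model
$g_i \sim N(\mu, \tau^2 + v_i)$. $\tau^2$ is estimated by iterated REML
(default) or Paule–Mandel (solving the generalized $Q(\tau^2) = k - 1$),
both to an absolute tolerance of $10^{-10}$ with at most 100 iterations and
truncation at zero. Confidence intervals and p-values use the
Hartung–Knapp adjustment: variance
$\sum_i w_i (g_i - \hat\mu)^2 / \big((k-1)\sum_i w_i\big)$ with
$w_i = 1/(v_i + \hat\tau^2)$, referred to a $t$ distribution with $k - 1$
degrees of freedom. With the small cohort counts typical of this field
($k \approx 3$–$10$), HK intervals are noticeably wider than
normal-approximation intervals and that is the point: the coverage
simulation in the test suite (10,000 five-study panels, true
$\tau^2 = 0.04$) lands between 93% and 97%. The same conservatism means a
single moderate effect among many null features does not always clear a
Benjamini–Hochberg $q < 0.1$ at $k = 5$; the pooled estimate itself is
stable long before the multiplicity-adjusted call is.

Features enter the meta-analysis only when they reach 10% prevalence and at
least five detections in one of the two class sets, and when at least three
cohorts contribute ten or more samples per class. Heterogeneity is reported
as $I^2 = \max(0, 100\,(Q - (k-1))/Q)$ from Cochran's fixed-effect $Q$.
Covariate-adjusted effects replace the two-group difference by the class
coefficient of an ordinary least-squares fit of $y$ on class, age, sex and
BMI within each cohort (squared standard error as sampling variance);
cohorts with fewer than ten complete-covariate rows or rank-deficient
designs are skipped with a warning, never silently imputed.

## Oral-typical signature and oral-to-gut scores

From participants with paired oral and stool samples, an SGB is
oral-typical when (1) it is exclusively oral in at least 20% of
participants, (2) it is found in both sites in fewer participants than
exclusively orally, and (3) it is exclusively in stool in fewer than 5%.
All three fractions share one denominator — participants with both samples —
because mixed denominators would make the criteria incomparable. Presence
means any nonzero profiler abundance. The boundary conventions are
"at least" for (1) and strictly "fewer than" for (3). Per stool sample, the
oral-to-gut *score* is the summed relative abundance of signature members
and the oral-to-gut *richness* their detected count.

## Community-level testing

Alpha diversity uses the Shannon index (natural log, via `vegan`) and
richness; beta diversity uses Bray–Curtis on relative abundances (raw, not
transformed — the standard choice; the transform switch exists upstream of
the distance call for users who want it). The blocked PERMANOVA computes
the usual decomposition ($SS_\text{total} = \sum_{i<j} d_{ij}^2 / N$,
within-group sums divided by group size) and builds the null by permuting
labels independently *within each cohort*, with the add-one p-value
$(1 + \#\{F^\ast \ge F\})/(1 + n_\text{perm})$, so $p$ can never be zero
and is bounded below by $1/(n_\text{perm}+1)$. One factor is tested at a
time; this matches the framework's use (condition, stage or location given
cohort structure). The implementation is checked in the tests against both
exhaustive within-block enumeration on small designs and
`vegan::adonis2` with restricted permutations.

## Classifier evaluation harness

Three designs, all leakage-proof by construction (sample identifiers shared
between a training pool and a test set raise an error):

* **per-dataset CV** — stratified 10-fold cross-validation repeated 20
  times, folds re-randomized each repeat, AUC computed per repeat on the
  pooled out-of-fold scores (pooling was chosen over per-fold averaging;
  with 10 folds of small cohorts, per-fold AUCs are too unstable);
* **across-dataset** — train on one cohort, test on another, for every
  ordered eligible pair;
* **LODO** — each cohort in turn is the test set and all others are pooled
  for training; cohorts failing validation eligibility (fewer than 15
  samples per class) still contribute to training pools.

The base learner is injected through a two-function interface
(`fit`/`score`), keeping the harness — the part this package is about —
independent of the classifier. The default mirrors a standard
metagenomics configuration: 1,000 trees, minimum five samples per leaf,
per-split feature count tuned over $\{\sqrt p, 0.1p, 0.2p, 0.3p\}$ by inner
5-fold CV on the training set only. Tests and the acceptance script use a
lighter forest (200 trees, untuned $\sqrt p$), which is ample for the
planted-signal recovery they measure. Feature sets `all`, `oral` and
`nonoral` differ in one step: subsets are renormalized per sample to [0, 1]
before the arcsine-square-root transform, so a subset classifier sees
compositions over its own feature space. AUC is the normalized
Mann–Whitney statistic with ties counted one half.

## Strain-level features

Marker-gene alignment columns become binary features in five stages, each
only ever shrinking the feature set (the funnel is logged):

1. **entropy screen** — per column, the major-allele frequency $p$ is taken
   over non-N symbols with the gap counted as an ordinary symbol (gaps are
   feature levels later, so they carry variability); keep columns with
   binary entropy $H(p) \ge 0.5$ bits, i.e. minor-symbol share above
   roughly 11%;
2. **pattern de-duplication** — samples are single-linkage clustered at
   pairwise distance (1 − identity over shared non-N columns) ≤ 0.05;
   within a cluster, columns inducing the same symbol-agnostic partition of
   the cluster's samples are duplicates and only the least-gapped column
   survives; a column kept in any cluster survives overall. The source
   description of this step admits more than one reading; this
   interpretation is explicit, tested, and can be switched off
   (`ani_dedup = FALSE`);
3. **one-hot encoding** — five features per column (A, C, G, T, gap); an N
   residue scores zero on all five, so per sample the row sum equals its
   number of non-N selected positions (a conservation law the tests assert
   after every stage);
4. **prevalence band** — features below 20% or above 80% prevalence in the
   control+CRC samples are removed (bounds inclusive for keeping, since the
   removal rules are strict inequalities); prevalence is computed on the
   pooled control+CRC set;
5. **greedy collinearity prune** — walking features in construction order
   (SGB, position, symbol), a feature is kept only if its absolute phi
   coefficient (the exact Pearson correlation of binary vectors, from the
   2×2 table) with every previously kept feature is ≤ 0.5.

The surviving binary matrix feeds a Jaccard-distance blocked PERMANOVA.
Samples with all-zero rows have no Jaccard distance and are excluded with a
warning.

## Signature analytics

Stage and disease signatures are compared by Jaccard similarity
($|A \cap B| / |A \cup B|$) and by the overlap fraction of a signature with
a reference panel. The cardiometabolic rank score computes, per feature and
per risk index, a partial Spearman correlation adjusted for sex, age and
BMI; ranks (normalized to [0, 1], unfavorable end at 1) are averaged within
each index category and then across categories, unweighted; features above
the third quartile of the global rank are selected, so the null selection
rate is one quarter by construction. Partial Spearman here ranks the
covariates as well as the two variables before residualizing — this is what
makes the statistic invariant to monotone covariate transformations and
makes adjusting a variable for itself yield exactly zero (flagged as
degenerate rather than returned as numerical noise). The disease-signature
recipe fits per-cohort OLS of transformed abundance on disease plus country
dummies (the country term is dropped in single-country cohorts), pools the
standardized coefficients with Paule–Mandel heterogeneity (Hartung–Knapp
intervals retained for internal consistency, switchable), and keeps
features with $q < 0.1$ detected in at least three cohorts.

## The synthetic multi-cohort generator

Every downstream stage is testable without external data because the
generator reproduces the statistical structure the analyses assume:

* **abundances** — per-feature log-normal latents
  ($\mu_f \sim N(0, 1.5)$, within-group log-SD 1 by default) with
  per-cohort, per-feature batch offsets ($SD = 0.5$), closed to sum one per
  sample, then zero-inflated by per-feature thresholding of the smallest
  values to a target prevalence (0.9 by default). Log-normal-plus-closure
  was chosen over a Dirichlet because it gives heavy-tailed marginals and
  lets batch offsets and planted effects act independently per feature;
* **planted effects** — a target Hedges' $g$ on the arcsine-square-root
  scale is mapped to a log-scale shift $\delta$ by the closed form
  $g = (r-1)\big/\big(\kappa\sqrt{(r^2+1)/2}\big)$ with $r = e^{\delta/2}$
  and $\kappa = \sqrt{e^{s^2/4}-1}$, derived from the log-normality of
  $\sqrt p$ and the small-$p$ approximation $\arcsin\sqrt p \approx
  \sqrt p$. The mapping ignores closure and zero-inflation, which is why
  recovery is asserted within bands ($\pm 0.15$ at $g = 0.6$; [0.7, 1.3]
  at $g = 1$) rather than exactly;
* **clinical structure** — CRC samples get stages (roughly the integrated
  corpus proportions, 8/21/22/24/25% for 0–IV) and tumor locations
  (35% right / 65% left); stage-trend features ramp linearly in stage rank;
  oral features can be multiplicatively boosted in CRC to emulate
  introgression. Age, sex and BMI are plain normal/Bernoulli draws
  (N(62, 11), 50/50, N(26, 4)) — within-cohort covariate distributions are
  a documented simplification, not an attempt at realism;
* **paired body sites** — per-SGB probabilities of oral-only / both /
  stool-only detection patterns, drawn per participant. The default truth
  is a bimodal tropism mixture (20% clearly oral-typical, the rest
  gut-or-shared), reflecting that body-site tropism in real paired cohorts
  is strongly bimodal; the true signature is computed from the
  probabilities themselves, so recovery can be scored exactly;
* **alignments** — clade consensus sequences with planted discriminating
  columns, per-sample substitutions, gaps and missing calls. Discriminating
  columns are only partially concordant with clades
  (`discriminating_noise = 0.2` by default): perfectly concordant columns
  are mutually collinear ($|\phi| = 1$) and the 0.5 prune would collapse
  them to a single feature, which no real marker-gene alignment does.

What passing tests on this generator do *not* show: robustness to
compositional artifacts stronger than closure, to taxonomic misassignment,
to covariate-confounded batch effects, or to real zero-generating
processes (the generator's zeros are thresholded, not sampled). Results on
real cohort collections depend on those, and on profiler choices upstream.

## Numerical choices and degenerate inputs

* Percentage-scale input tables are auto-detected (any column sum > 1.5)
  and rescaled to fractions; the transform clips inputs within $10^{-12}$
  of [0, 1] and errors beyond.
* Zero pooled SD in `hedges_g` returns $g = 0$ with the mean-term variance,
  flagged degenerate; pooling refuses all-zero variances; $k = 1$ "pools"
  to the single study with a normal interval, flagged unpooled.
* The sample odds ratio in the enrichment test is $(ad)/(bc)$ with the
  $\infty$ convention when $bc = 0$; a zero margin gives $p = 1$ and an
  undefined odds ratio. The two-sided p sums hypergeometric probabilities
  no larger than the observed table's (with a $1 + 10^{-7}$ tie guard, the
  same convention as `fisher.test`).
* All simulations and permutation streams run off a single integer seed;
  fixed seed means byte-identical output, which the tests assert literally.
* Problem sizes in the shipped tests and acceptance script — 2,000-feature
  null panels, 10,000-rep coverage simulations, five cohorts of 100+100,
  495 paired participants, 80-sequence alignments — were chosen as the
  smallest designs at which the calibration bands are tight enough to be
  meaningful.

## Known limitations

* One-factor PERMANOVA only; covariate-adjusted community tests would need
  a sequential multi-factor extension.
* The pattern de-duplication stage is one defensible reading of an
  ambiguous procedure; the switch exists because the reading is a judgment
  call.
* The cardiometabolic index panel itself is not shipped; the operation
  takes arbitrary index matrices.
* Eukaryotic/functional profiles are consumed through the same generic
  table reader with no format-specific handling.
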