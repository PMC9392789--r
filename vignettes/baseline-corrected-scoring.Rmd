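---
title: "Baseline-corrected cell cycle scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Baseline-corrected cell cycle scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bccs)
library(dplyr)
```

## The problem and the model

Bulk tumour transcriptomes are usually scored for proliferation in absolute
terms, which conflates two things: how active the tumour is, and how active
its tissue of origin already was. This package reclassifies tumour
cell-cycle activity *relative to the normal tissue it arose from*.

The score itself is deliberately simple. For a signature gene set $S$ and
sample $j$ with log-expression $x_{gj}$,

$$\mathrm{CCS}_j \;=\; \sum_{g \in S} x_{gj},$$

a plain sum with no weighting. This presumes the expression matrix is
already co-normalised across studies on a log2-like scale so that values
are directly comparable between samples — the loaders validate finiteness
but deliberately do not transform. The correction subtracts the per-tissue
median over *normal reference samples only* (adjacent-normal tumour-study
samples are retained for plotting but never enter the baseline, since their
microenvironment makes them a biased reference), then multiplies by tumour
purity $\rho_j \in [0,1]$:

$$\mathrm{BC\text{-}CCS}_j \;=\; \bigl(\mathrm{CCS}_j - \mathrm{med}\,
\mathrm{CCS}_{\text{normal},\,t(j)}\bigr)\,\rho_j .$$

The order of operations is fixed — subtract, multiply, min–max scale — and
the scaled variant exists purely for comparability of plots; every test
statistic uses the unscaled values. Purity multiplication shrinks the
corrected score of impure tumours toward zero on both sides, which is the
intended reading: the observed expression shift is attributed to the
malignant fraction of the sample. Tumours with no purity value are dropped
by default (with a count) rather than imputed; an impute-by-cancer-type-mean
policy is available but changes group medians, so it is opt-in.

Median, not mean, anchors the baseline because normal-tissue score
distributions are small-sample and occasionally skewed; an even sample
count takes the midpoint of the central pair. The weakness of this choice
is inherited honestly: a tissue with very few normals yields an unstable
baseline, and `compute_baselines()` reports `n_normals` per tissue so users
can see which baselines are fragile.

## Quadrants

`classify_quadrants()` summarises each tissue by the median scaled score of
its normals (x) and of its tumours (y), min–max rescales each axis across
tissues, and cuts both axes at a threshold (default 0.5). The threshold is
a formalisation of what is otherwise read off a scatterplot by eye; it is
exposed in the configuration, and a median falling exactly on the cut is
assigned HIGH so the rule is total. Quadrant membership is invariant to any
common affine transform of the raw scores, which is the property that makes
the visual convention well-defined.

## Group comparisons

Two disjoint sets of cancer types — the lowest and highest corrected
activity groups — are compared feature by feature.

**Binary genomic features.** Displayed frequencies are macro-averaged over
cancer types (the unweighted mean of within-type frequencies, so a large
cancer type cannot dominate the group's percentage), while the Fisher exact
test is computed on pooled per-group counts. These two conventions coexist
deliberately: a single p-value per feature implies pooled testing, whereas
size-adjusted percentages are the fair display. A cancer-type-stratified
Cochran–Mantel–Haenszel test is available (`stratified = TRUE`) for users
worried about type-composition confounding; it is not the default because
pooled counts are what the two-sided Fisher test describes. The Fisher
p-value is computed by direct hypergeometric enumeration (the sum of all
conditional table probabilities not exceeding the observed one, with the
conventional $1+10^{-7}$ tie slack); this is the textbook definition, is
verified exhaustively against an independent enumeration for every table
with $n \le 50$, and is fast enough to sweep hundreds of thousands of
tables. The conditional-MLE odds ratio is reported alongside. Arm-level
gains ($+1$) and losses ($-1$) are tested separately per arm, with BH-FDR
within each direction, because a single arm can plausibly be enriched for
loss in one group and gain in the other. Direction filtering ("higher in
Group 2") is a post-hoc filter on macro-averaged frequencies, never a
one-sided test.

**Expression.** Each gene is fitted by OLS on
[intercept, Group-2 indicator, cancer-type dummies, covariate gene], with
one reference cancer type per group dropped from the dummies — with full
dummies the group indicator is their sum and the design is aliased by
construction. The covariate gene (default ESR1) enters as its own
expression row, adjusting for hormone-signalling differences; its absence
is a hard error rather than a silent non-adjustment. Residual variances are
shrunk by empirical Bayes under the scaled-F model
$s^2_g \sim s_0^2 F(d_g, d_0)$, with $(d_0, s_0^2)$ estimated by moment
matching of $\log s^2_g$ (trigamma-inverse solve). The implementation is
validated three ways: $d_0 = 0$ reproduces per-gene OLS t exactly,
$d_0 = \infty$ pools every gene to the common prior variance, and the
estimated-prior path agrees with the reference empirical-Bayes
implementation (limma) to near machine precision on the same design.
Near-zero residual variances (e.g. the covariate gene regressed on itself)
are floored at $10^{-5}\times$ the median variance before moment matching,
matching reference behaviour. Significance combines a strict
$|\log_2 \mathrm{FC}| > 2$ with FDR < 5%; a gene at exactly the cut is not
significant.

**Enrichment.** Preranked GSEA uses the weighted Kolmogorov–Smirnov
running sum with weight $|r_g|$ (exponent 1). The default ranking statistic
is $\mathrm{sign}(\log_2\mathrm{FC})\cdot(-\log_{10} p)$, combining effect
direction and significance; pure-fold-change and t-statistic rankings are
switchable. Ties are broken by $|\log_2\mathrm{FC}|$ then gene id so the
ranking is a deterministic function of the results. The null is gene-label
permutation (sampled set positions, shared across sets of equal size),
$p$ is empirical with the $+1$ correction against the sign-matched null,
NES divides ES by the mean $|$null ES$|$ of matching sign, and FDR is BH
over set-level p-values — simpler and better-defined than the classic
positive/negative permutation FDR, at the cost of some conservatism for
small set collections. When the positive and negative maximum deviations of
the running sum tie exactly (possible on short rankings), the positive
extremum wins, with a $10^{-12}$ tolerance so floating-point noise cannot
flip the sign. Sets with fewer than 5 ranked genes are skipped with a
warning; fewer than 100 permutations is an error.

## Embedding QC and outlier flagging

Batch-effect assessment uses PCA (per-gene centring, component signs fixed
by making the largest-magnitude loading positive, so coordinates are
reproducible) over either the most variable genes — plain variance, since
nothing more elaborate is warranted for co-normalised log expression — or
the signature genes, plus a 2-D UMAP (library defaults, fixed seed,
single-threaded so coordinates are reproducible on a platform). Outlier
removal, done by manual inspection in typical practice, is formalised as a
rule: squared Mahalanobis distance on the first two components under a
high-breakdown MCD location/scatter estimate, flagging beyond the
$\chi^2_2$ quantile at $1-\alpha$ (default $\alpha = 0.001$). The MCD
subset search is internally seeded so flagging is a pure function of the
embedding. On clean Gaussian data the empirical flagging rate is close to
$\alpha$ but slightly above it (the robust estimate shrinks the covariance);
the suite asserts a generous binomial envelope rather than exact calibration.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes,
with Gaussian log-scale expression throughout — the pipeline consumes
already-normalised log expression, so no count-level realism (library
size, dispersion, batch) is attempted, and conclusions from passing tests
transfer to real data only insofar as real data meet the normalisation
assumption.

Per tissue $t$: signature genes of normals are
$N(\mu_t, \sigma^2)$ and of tumours $N(\mu_t + u_t, \sigma^2)$, plus a
shared per-sample latent $N(0, \sigma_\ell^2)$ that also drives a disjoint
proliferation metagene (so signature and metagene correlate within tissue,
mirroring the strong signature–metagene correlation seen in practice).
Default study conditions: 8 tissues spanning high-baseline/low-uplift
(head & neck: $\mu = 8$, $u = 0.6$) to low-baseline/high-uplift
(gynaecological: $\mu = 1.5$–$2$, $u = 6.5$–$7$), 30 normals and 100
tumours per tissue, $\sigma = 1$, $\sigma_\ell = 0.5$. The gynaecological
uplifts are large enough that those tumours are simultaneously the highest
*corrected* scores and high in *absolute* terms, landing in the
low-normal/high-tumour quadrant — the qualitative configuration the method
exists to expose. Purity is Beta(5, 2.5) (mean $2/3$, typical of bulk
tumour cohorts); mutations are Bernoulli with a configurable odds
multiplier on the high group (default: one planted gene at odds 3 over a
15% base, against a backdrop including a TP53-like gene at 45%);
arm calls plant losses on 16q/8p (0.6 vs 0.2) and gains on 3q/1q
(0.5 vs 0.2) over a 10% background, losses emitted as $-1$; 30 DE genes
are planted at $\log_2\mathrm{FC} = 3$ in high-group tumours along with a
hormone module (ESR1, PGR, AR plus members) shifted by 1.5; and one
activity-tracking gene is generated at a target correlation of 0.6 with
the per-sample (uplift + latent) signal. One global seed drives
deterministic per-component sub-streams, so adding a component never
perturbs earlier draws and equal seeds give bitwise-equal cohorts.

A separate deterministic fixture, `generate_consort_fixture()`, reproduces
published cohort-selection bookkeeping exactly (19,131 samples; class
totals 734 / 92 / 802 / 4,043 / 319 / 24; 13,460 and 13,117 retained;
4,979 normals and 8,138 tumours). Only the class totals are published; the
tissue composition inside each class is synthetic and labelled as such.

## Numerical and testing choices

Problem sizes in the test-suite and acceptance runs are chosen to make
recovery statistically decisive while staying desk-scale: 8 tissues × 100
tumours for rank recovery, 250 tumours per group × 200 replicates for
arm-level power, 100 tumours per group × 50 seeds for DE recovery, an
exhaustive 313,600-table sweep for the Fisher oracle, and 2,000 null genes
for moderated-t calibration. Exact-test p-values on discrete data are
conservative by construction, so calibration is asserted as
$P(p \le a) \le a$ plus FDR control under label permutation, while the
continuous moderated-t p-values are asserted uniform under the null by a
Kolmogorov–Smirnov test.

## Known limitations

Baselines assume each normal tissue is a single homogeneous population;
tissues with few normals give unstable medians (reported, not corrected).
The expression model is Gaussian and batch-free, so the embedding-QC
machinery is exercised on structure the generator does not adversarially
produce. Group membership, thresholds (FDR 5%/10%, $|\log_2\mathrm{FC}| > 2$,
rho 0.3, quadrant 0.5) are conventions exposed in `run_config()` rather
than quantities the package can justify from data. Per-sample baseline
matching, menopausal stratification and count-level simulation are out of
scope.
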