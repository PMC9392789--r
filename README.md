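# bccs: baseline-corrected cell cycle scoring

Tumours differ enormously in how fast they cycle — but so do the normal
tissues they arise from. A tumour type with modest absolute cell-cycle
activity can still represent a dramatic *increase* over its tissue of origin,
while a tumour in an already fast-cycling tissue may have little room left to
accelerate. `bccs` implements the analysis that makes this comparison
explicit for paired normal/tumour bulk RNA-seq cohorts (GTEx-style normals
plus TCGA-style tumours co-normalised on a log2 scale), and is aimed at
computational cancer biologists who want a tested, reusable version of the
whole chain rather than one-off scripts.

## The method

For a cell-cycle gene signature *S* and sample *j*, the **cell cycle score**
is the plain sum of log-expression over the signature genes:

```
CCS_j = Σ_{g ∈ S} x_gj
```

Each tumour is then corrected by the median score of its normal
tissue-of-origin (normal reference samples only) and by its malignant-cell
fraction ρ_j (tumour purity, supplied as input), and finally min–max scaled:

```
BC-CCS_j = (CCS_j − median{ CCS of normal tissue t(j) }) × ρ_j   →  scaled to [0, 1]
```

Downstream, the pipeline compares the cancer types with the lowest and
highest corrected activity (Group 1 vs Group 2) at three levels:

- **driver-gene mutations** and **chromosome-arm gains/losses** — two-sided
  Fisher exact tests on pooled counts, frequencies reported as
  macro-averages over cancer types, Benjamini–Hochberg FDR (gains and losses
  tested separately per arm);
- **expression** — per-gene linear models with cancer-type dummies and an
  ESR1 covariate, empirical-Bayes moderated t-statistics (moment-matched
  variance prior), volcano partition at |log2FC| > 2 and FDR < 5%;
- **pathways** — preranked gene-set enrichment (weighted running-sum ES,
  gene-label permutation null, FDR < 10%), plus per-gene Spearman
  correlation to the corrected score with the conventional rho > 0.3
  reference line.

A synthetic-cohort generator (`generate_cohort()`) produces manifest,
expression, purity, mutation and arm-call tables with known ground truth —
tissue baselines, tumour uplifts, planted mutation/arm enrichments and DE
genes — so every stage of the pipeline is validated by parameter recovery.

## Worked example

```r
library(bccs)
library(dplyr)

co <- generate_cohort(synthetic_config(seed = 42))
scores    <- compute_signature_score(co$expression, co$gene_sets$CCS) |> minmax_rescale()
baselines <- compute_baselines(scores, co$manifest)
bc        <- compute_bc_ccs(scores, baselines, co$manifest) |> adjust_for_purity(co$purity)

bc |> group_by(cancer_type) |>
  summarise(median_bc_ccs = median(bc_purity_adjusted)) |>
  arrange(desc(median_bc_ccs))
#>   cancer_type median_bc_ccs
#> 1 OV                  242.
#> 2 CESC                225.
#> 3 LUAD                 67.8
#> ...
#> 8 HNSC                 15.4
```

The gynaecological cancer types (OV, CESC) — generated with low normal
baselines but large tumour uplifts — come out with the highest corrected
scores, while head & neck tumours, whose normal tissue already cycles
fastest, come out lowest even though their *absolute* scores are among the
highest. The quadrant view makes the same point per tissue:

```r
classify_quadrants(scores, scores, co$manifest)
#>   tissue            median_normal_scaled median_tumor_scaled quadrant
#> 1 Bladder                          0.523               0.578 HIGH_HIGH
#> 2 Cervix                           0.041               0.959 LOW_HIGH
#> 3 HeadNeck                         1                   0.968 HIGH_HIGH
#> 4 KidneyChromophobe                0.353               0.129 LOW_LOW
#> ...
```

Group comparison then recovers the planted genomic differences:

```r
g   <- group_assignment(group1 = c("HNSC", "KICH", "KIRP", "UCEC"),
                        group2 = c("CESC", "OV"))
arm <- compare_arm_calls(co$arm_calls, co$manifest, g)
head(higher_in_g2(arm), 4)
#>   feature_id direction adj_freq_g1 adj_freq_g2 ...        q
#> 1 16q_loss   loss            21           66.5     4.9e-26
#> 2 8p_loss    loss            17.8         60       ...
#> 3 3q_gain    gain            17.8         56.5     ...
#> 4 1q_gain    gain            19           51       ...

de <- fit_moderated_de(co$expression, co$manifest, g)
de
#> Moderated DE fit: 414 genes, 400 vs 200 samples, df_resid = 593, prior df = 7.014
#> Significant (|log2FC| > 2 & FDR < 0.05): 31 up, 0 down
```

The 16q and 8p losses and 3q/1q gains are exactly the enrichments the
generator planted (rates 0.6 and 0.5 vs 0.2), and the 31 upregulated genes
contain all 30 planted DE genes. `autoplot()` methods exist for quadrant
tables, DE fits and embeddings; `tidy()`/`glance()` for the DE fit.

`run_pipeline(run_config(...))` chains all of the above (filtering →
scoring → correction → quadrants → genomic comparison → DE → enrichment)
and writes one TSV per stage plus a JSON run report.

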