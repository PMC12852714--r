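# sigratio

Gene-signature correlation-ratio scoring and tumor microenvironment
quantification for bulk and pseudobulk transcriptomics.

## What it does, and for whom

When a surface antigen such as CD24 (a "don't eat me" signal read by
Siglec-10 on macrophages and microglia) is being evaluated as a
therapeutic target across brain-tumor subgroups, a recurring analysis
pattern appears: correlate the gene of interest with curated gene
signatures, classify each correlation into published strength tiers, and
summarise the signature as a single ratio. `sigratio` packages that
analysis — and the statistics around it — for computational biologists
who want it reproducible and testable:

* **Tier classification** of Spearman correlations. The strongest
  satisfied tier wins: strong when |ρ| ≥ 0.50 and p < 0.05, moderate when
  |ρ| ≥ 0.30 and p < 0.05, weak when |ρ| ≥ 0.26 and p < 0.001 (mirrored
  for negative ρ), else none.
* **Correlation-ratio score** for a gene of interest *g* against a
  signature *S*:

  ratio = #\{sign-matched correlated genes\} / (|S| − #missing − 1[g ∈ S])

  The denominator adjustments generalize the published divide-by-8 (two
  genes absent from a platform) and divide-by-11 (IDO1 absent from the M1
  profile; TREM2 scored against the M2 profile that contains it) rules.
* **Built-in signatures**: the 10-gene high-risk and low-risk prognostic
  signatures, the 12-gene M1/M2 macrophage profiles, and a
  tumor/microglia/macrophage marker panel — transcribed verbatim.
* **Preranked enrichment** (weighted Kolmogorov–Smirnov ES, gene-tag
  permutation NES) with subtype assignment by maximum NES.
* **Survival statistics** from first principles: Kaplan–Meier
  product-limit curves with medians, log-rank (Mantel–Cox) test,
  administrative censoring at a horizon (default 100 days).
* **Mann–Whitney U** with exact small-sample enumeration.
* **Image quantification**: tumor masks from DAPI, stained-area/tumor-area
  ratios at a fixed shared threshold, areas in mm², nucleus counting with
  watershed splitting, stain-per-nucleus for cultured cells.
* **Seeded synthetic-data generators** (Gaussian-copula expression with
  planted Spearman structure, exponential survival, two-channel stain
  images, subtype-shifted panels) with exact ground truth, so the whole
  pipeline validates end-to-end offline.

## Worked example

```r
library(sigratio)

## 240 samples in two subgroups; 7 of the 10 high-risk genes planted at
## Spearman rho = 0.6 with CD24
sim <- simulateExpression(nSamples = c(SHH = 120, Group3 = 120),
                          plantedRho = 0.6, nPlanted = 7,
                          backgroundGenes = 20, seed = 42)
ratioScore(sim$expr, "CD24", getSignature("high_risk"), "positive",
           subgroup = "SHH")
#> RatioScore: CD24 vs high_risk (positive)
#>   ratio 7/10 = 0.700  [SHH, n = 120]
```

The planted 7-of-10 design is recovered exactly: 7 signature genes reach
a positive tier, the denominator stays 10 (no missing genes, no
self-exclusion), ratio 0.70.

```r
## two-arm survival, hazards 0.05 vs 0.02 per day, censored at 100 days
rec <- simulateSurvival(c(control = 28, treated = 28),
                        c(control = 0.05, treated = 0.02), seed = 42)
out <- compareSurvival(rec, "control", "treated")
out$test
#> TestResult (chi_square): statistic = 8.91441, two-sided p = 0.002829, n = 28/28
medianSurvival(out$curves$control); medianSurvival(out$curves$treated)
#> [1] 12.44221
#> [1] 28.46928
```

The halved-and-again hazard more than doubles the median (12.4 → 28.5
days) and the Mantel–Cox test detects it (χ² = 8.9, p = 0.0028).

```r
## synthetic two-channel section: 30% tumor, 25% of it marker-positive
img <- simulateStainImage(tumorFraction = 0.3, stainedFraction = 0.25,
                          nNuclei = 40, seed = 42)
tm <- tumorMask(img$image@nuclear, pixelSizeUm = 1)
tm
#> MaskResult: 19753 px (0.01975 mm^2), threshold 0.3027, shape 256 x 256
stainedAreaRatio(img$image@marker, tm, threshold = 0.45)
#> [1] 0.2489...   # planted ground truth: 0.250
```

See `vignettes/signature-correlation-scoring.Rmd` for the model details,
parameter meanings, numerical conventions and known limitations.

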