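---
title: "Signature correlation-ratio scoring: models, parameters and design"
author: "sigratio maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature correlation-ratio scoring: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigratio)
```

# The problem

Malignant brain tumors (medulloblastoma in children, glioblastoma in
adults) divide into molecular subgroups with distinct prognosis, and the
CD24/Siglec-10 axis — CD24 on tumor cells acting as a "don't eat me"
signal to Siglec-10 on macrophages and microglia — varies across them.
`sigratio` implements the computational toolkit for studying such an axis
in bulk or pseudobulk transcriptomics:

1. a **signature correlation-ratio score** summarising how consistently a
   gene of interest co-varies with a prognostic or cell-state gene
   signature,
2. **M1/M2 macrophage-profile ratios** with explicit denominator
   adjustments,
3. **preranked gene-set enrichment** with subtype assignment by maximum
   normalized enrichment score,
4. the **survival** (Kaplan-Meier / log-rank) and **group-difference**
   (Mann-Whitney U) statistics of an in vivo study arm, and
5. **fluorescence image quantification** (stained-area ratios, tumor area
   in mm², stain per nucleus).

Every stage is exercised end-to-end on seeded synthetic data with known
ground truth, so the whole pipeline is testable without any external
download.

# The correlation-ratio score

For a gene of interest $g$ and a signature $S = \{s_1, \dots, s_m\}$, each
pair $(g, s_i)$ receives a Spearman rank correlation $\rho_i$ with
two-sided p-value $p_i$, classified into a seven-level tier scale:

| tier | rule |
|---|---|
| strong positive | $\rho \ge 0.50$ and $p < 0.05$ |
| moderate positive | $\rho \ge 0.30$ and $p < 0.05$ |
| weak positive | $\rho \ge 0.26$ and $p < 0.001$ |
| none | otherwise |

with the mirrored rules for negative correlations. R-thresholds are
inclusive, p-thresholds strict, and the *strongest* satisfied tier wins
(the scale is mutually exclusive, as in the published color scale). Note
the deliberate gap: $\rho \in [0.26, 0.30)$ with $p \in [0.001, 0.05)$ is
`none` under a strict reading of the printed rules.
`TierThresholds(relaxWeakP = TRUE)` widens the weak tier's p cutoff to
0.05 for sensitivity analysis; the default keeps the strict reading.

The ratio score is

$$ R(g, S) = \frac{\#\{i : \text{tier}(\rho_i, p_i)\ \text{matches the
requested sign}\}}{m - \#\text{missing} - \mathbf{1}[g \in S]} $$

Only sign-matched tiers count (a negative correlation never counts toward
a positive-direction ratio). The denominator adjustments generalize the
published rules: two genes missing from a platform turn a 10-gene
denominator into 8; a 12-gene macrophage profile missing IDO1 is scored
over 11; and TREM2 scored against the M2 profile that contains it is
scored over 11 (self-exclusion). Whether self-exclusion was applied and
which genes were missing are always recorded on the returned `RatioScore`.

```{r ratio-demo}
sim <- simulateExpression(nSamples = 200, plantedRho = 0.6, nPlanted = 7,
                          backgroundGenes = 0, seed = 1)
ratioScore(sim$expr, "CD24", getSignature("high_risk"), "positive")
```

The built-in registry (`builtinSignatures()`) transcribes the curated
10-gene high-risk and low-risk prognostic signatures, the 12-gene M1 and
M2 macrophage profiles, and a marker panel, verbatim — including the
symbols `ITGB` and `ZPF3`, which have no unambiguous current HGNC match.
They are deliberately left uncorrected (no alias expansion): scores must
reflect the lists as published, and a platform that lacks them simply
triggers the missing-gene denominator rule. All symbol matching is
case-insensitive after upper-casing, with hyphens stripped (`SIGLEC-10`
and `SIGLEC10` are the same symbol), because platforms disagree on
hyphenation.

# Statistical primitives

The rank statistics are implemented from first principles, with
well-established library routines used as *independent oracles* in the
test suite rather than as the implementation.

**Spearman.** $\rho$ is the Pearson correlation of midranks. For
$n \le 9$ without ties the two-sided p is exact, by enumeration of all
$n!$ rank pairings; otherwise the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom is used —
the dominant convention in the statistics packages used for this kind of
analysis, and the tier rules only threshold p. With ties, enumeration is
skipped even at small $n$ (the conditional permutation distribution given
midranks is no longer the textbook null) and the t-approximation is used.
A perfect correlation under the t-approximation reports the smallest
representable positive double rather than an exact zero.

**Mann-Whitney U.** $U = \#\{(i,j): x_i > y_j\} + \tfrac12\#\text{ties}$.
Exact two-sided p by enumeration of all $\binom{n_1+n_2}{n_1}$ group
assignments when $n_1 + n_2 \le 12$ and there are no ties (rejecting on
$|U - n_1 n_2/2|$, which matches the symmetric exact distribution);
otherwise the normal approximation with tie correction and continuity
correction. The method actually used is recorded on every `TestResult`.

**Kaplan-Meier.** Standard product-limit estimator. Subjects censored at
an event time remain in the risk set at that time (events precede
censorings within a tied time). The median convention is the *first event
time with* $S(t) \le 0.5$, which resolves the $S = 0.5$ plateau
deterministically; it is a declared convention, not an inference about
any particular software.

**Log-rank (Mantel-Cox).** $\chi^2 = (\sum_t (O_t - E_t))^2 / \sum_t V_t$
over distinct event times with the hypergeometric variance, one degree of
freedom. Calibration is verified by simulation: under the null (equal
exponential hazards, administrative censoring at 100 days, 20 subjects
per arm) the empirical type-I error at $\alpha = 0.05$ lands within
[0.03, 0.07] over 2000 replicates.

# Preranked enrichment and subtype calls

`rankSample()` orders a sample's genes by expression descending, ties
broken alphabetically — deterministic by construction. The ranking metric
is the normalized expression value itself; this mirrors feeding
expression directly to a preranked tool and is a documented caveat (a
differential statistic would weight the tails differently).
`enrichmentScore()` is the classic weighted Kolmogorov-Smirnov running
sum (hits weighted by $|metric|^p$ normalized to the hit total, misses by
$1/(N-k)$); the implementation evaluates only the $2k$ candidate extrema
adjacent to hit positions, which is exact and $O(k)$ after the membership
scan. `normalizedES()` uses the gene-tag permutation null (random gene
sets of equal size), $\mathrm{NES} = ES / \overline{|ES_{null,\,same\,
sign}|}$, and an add-one-corrected empirical p with floor
$1/(n_{perm}+1)$. Probe-level "collapse" machinery is deliberately
replaced by symbol matching: inputs here are already symbol-keyed.

`assignSubtype()` designates the signature with the highest NES as the
subtype; an exact tie returns `"ambiguous"`. Subtype gene sets are
supplied by the user (GMT via `readGmt()`) or generated synthetically —
the package ships no retrieved signature databases.

# Survival and viability stages

`compareSurvival()` applies administrative censoring — any subject beyond
the horizon (default 100 days, a standard monitoring window) is censored
*at* the horizon even if its record carries an event flag — then runs the
log-rank test and returns both KM curves with medians.

`normalizeViability()` uses reference-wavelength subtraction (OD 540 nm
minus OD 650 nm), the standard MTT convention, chosen because plate
readers report both wavelengths but no combination formula is universal;
the corrected OD is normalized to the mean of untreated wells within the
same timepoint (and plate, when given). `doseAtFraction()` finds the
first downward crossing of a target viability (default 0.5, the "50%
cell death" line) by linear interpolation in log10-dose; non-monotonic
curves still return the first crossing but are flagged.

# Image quantification

The published workflow thresholds a "pseudocolor" in proprietary
software; here that becomes an explicit fixed intensity threshold shared
across every image of a comparison (honoring "same intensity settings
irrespective of treatment"), with Otsu's method offered for the tumor
mask only. Conventions: thresholds inclusive ($\ge$), 8-connected
components, hole filling before labeling, components smaller than a
configurable minimum (default 50 px for tumor masks, 20 px for nuclei)
removed, and distance-transform watershed splitting of touching nuclei on
by default. Areas convert as
$\mathrm{mm}^2 = \mathrm{px} \cdot (\mathrm{pixel\ size\ in\ \mu m}/1000)^2$.
Manual masks can be supplied directly as a `MaskResult` when segmentation
is done elsewhere.

# The synthetic-data generators

The generators define the study conditions under which the package is
validated; their defaults are fixed once and are not tuned per test.

**Expression.** Gaussian-copula sampling. A latent standard normal factor
plays the gene of interest; each planted signature gene gets latent
Pearson correlation $r = 2\sin(\pi\rho_s/6)$ with it — the exact
conversion for the bivariate normal copula, so the Spearman correlation
after any monotone marginal transform is exactly $\rho_s$. A note on
geometry: a "star" correlation matrix with $k$ genes each correlated $r$
with the hub and zero with each other stops being positive definite once
$kr^2 > 1$ — impossible for, say, ten genes at $\rho_s = 0.6$. The
generator therefore uses the single-factor construction
$z_j = r z_0 + \sqrt{1-r^2}\,\varepsilon_j$, which delivers the exact
requested hub correlations for any $k$ (planted genes are mutually
correlated $r^2$, a property real co-regulated signatures share), and
keeps background genes independent. The default marginal is lognormal
with log-SD 1, mimicking the positivity and right skew of normalized
expression; marginal choice provably does not affect any rank-based
quantity downstream.

**Survival.** Exponential event times with group-specific hazards and
administrative censoring at 100 days. The defaults used in validation
(hazard 0.05/day, i.e. median ~13.9 days, against 0.025/day, n = 20 per
arm) echo the scale of an orthotopic glioma model where control medians
fall near four weeks and monitoring ends at 100 days.

**Images.** A wobbly-disk tumor blob (harmonic perturbation of a disk
whose area matches the requested tumor fraction), a stained subregion of
*exactly* the requested pixel count selected by a smooth random field (so
it is blobby, not salt-and-pepper), non-overlapping nucleus disks placed
by rejection sampling (an error is raised when the packing is
infeasible), and Gaussian intensity noise (default SD 0.02 on a [0, 1]
scale). Ground-truth masks and counts are returned exactly.

**Subtype panels.** Disjoint synthetic signatures (default 3 × 50 genes
over a 1000-gene universe); each sample's true-subtype genes are
up-shifted by `shiftSd` (default 2) standard deviations in log space.
`shiftSd = 0` removes all signal, putting assignment at chance.

What the generators deliberately do **not** emulate: probe effects, batch
effects, inter-gene correlation beyond the planted structure, cell-type
mixtures, autofluorescence gradients, or uneven illumination. Passing
recovery tests on this synthetic data therefore demonstrates correctness
of the *computations*, not robustness to every artifact of real platforms
— the usual scope of a validation suite built on simulation.

# Problem sizes and numerical choices

The validation suite uses: 1000 random vectors for the Spearman oracle
comparison (agreement to 1e-12), full enumeration up to $n = 7$ for exact
p-values, 100 replicates × k ∈ {0, 3, 7, 10} at n = 200 samples for
ratio recovery, 2000 null simulations for log-rank calibration, 60
samples at 500 permutations for subtype recovery, and 100 synthetic
images (192 × 192 px) spanning stained fractions 0.05–0.95 for image
recovery. `scripts/acceptance.R` re-runs scaled versions of the same
experiments from a command-line seed.

Numerical conventions worth knowing: floating-point comparisons against
tier thresholds are raw (no epsilon — thresholds are config values, not
measurements); the exact-p enumerations use a 1e-12 slack when comparing
permutation statistics to the observed one so ties in the permutation
distribution are counted; survival medians use `S(t) <= 0.5 + 1e-12`;
enrichment ties between equal positive and negative extrema resolve to
the positive score; and all seeded helpers save and restore the caller's
RNG state, so library code never perturbs a user's reproducibility.

# Known limitations

* The ratio score inherits the published thresholds; no multiple-testing
  correction is applied across a gene panel (none is applied in the
  source analysis it reproduces), and the tier gap region is a faithful
  strict reading rather than a statistical recommendation.
* Exact Spearman p-values are unavailable in the presence of ties (the
  t-approximation is used); for $n < 10$ with heavy ties this is a known
  weak spot of every closed-form approach.
* Preranked enrichment on raw expression values ranks housekeeping genes
  highly in every sample; subtype NES values are comparable within a
  sample but not across cohorts.
* The image pipeline assumes a single dominant tumor region per section
  and roughly uniform background; it does not register serial sections or
  classify cell types.
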