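---
title: "chronoclass: statistical methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chronoclass: statistical methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronoclass)
```

# The model

Each gene's normalized log2 ratio (sample against a common reference
pool) is modelled as Gaussian around one of three age-category means —
fetal (F), young (Y), adult (A) — with a common within-gene variance:

$$x_{gj} = \mu_{g,c(j)} + \varepsilon_{gj}, \qquad
  \varepsilon_{gj} \sim N(0, \sigma_g^2),$$

where $c(j)$ is the category of sample $j$. The scientific object of
interest is the *weak ordering* of $(\mu_F, \mu_Y, \mu_A)$: which means
coincide, and how the distinct ones are ordered. Three items admit 13
weak orderings (6 total orders, 6 with one equality, 1 all-equal);
`enumerateModelClasses()` lists them with a fixed canonical numbering in
which the single-equality classes come first (fetal apart, adult apart,
young apart, each in both directions), the monotone increase `F<Y<A` is
class 7, and the all-equal class is last.

## Significance and backward selection

Per gene, significance is measured by the classical one-way ANOVA
omnibus p-value of the full three-mean model against the all-equal
model, computed with unweighted-cell-mean F statistics so unbalanced
designs (the emulated study has 36/9/2 samples per category) are handled
exactly. This p-value is uniform on (0, 1) under the all-equal null —
the property the permutation-based FDR machinery and its diagnostics
rest on — and it is the quantity reported in `classifyGenes()$p_value`
and fed to `calibrateThreshold()`.

The *structure* of a significant gene is then chosen by backward model
selection: starting from the full three-mean model, the two merges of
category means that are adjacent in the estimated-mean order are tested
by partial F-tests against the full model, and the merge with the larger
p-value is applied when that p-value exceeds the working level
$\alpha$. Merging only adjacent means is not a restriction: merging two
non-adjacent means cannot produce a weak ordering. The selection is
*protected*: a gene whose omnibus p-value is at or below $\alpha$ never
collapses to the all-equal class — it retains at least a two-group
structure, so every significant gene receives a directional class label,
and the significant/non-significant split depends on the omnibus
p-value alone. An early design variant used the minimum partial-F
p-value along the greedy merge path as the gene-level significance
measure; simulation showed that quantity to be markedly non-uniform
under the null (inflated roughly three-fold at small p), which breaks
FDR calibration diagnostics, so the omnibus-gated protected variant was
adopted. The partial-F p-values along the path are still reported
(`p_merge`, `p_collapse`) for transparency.

Ties in estimated group means are resolved conservatively: exactly tied
means are merged, and the reported pattern carries the equality. Genes
with zero residual variance are flagged `exact_fit` (p = 0 when the
means differ, 1 otherwise); genes missing a whole category are fitted on
the present categories and flagged.

Two independently coded routes compute the same fit — a vectorized
matrix-algebra engine (`classifyGenes()`) and a scalar `lm()`/`anova()`
route (`fitGene()`) — and the test suite checks them against each other
and against an exhaustive oracle that fits all five mean partitions and
picks the most parsimonious one not rejected against the full model.

## FDR calibration

The multiple-testing correction is simulation-based, in the style of
SAM. Null datasets permute the age-category labels across samples as a
whole (one permutation applied to every gene), preserving the gene-gene
correlation structure; each simulation recomputes all omnibus p-values.
At a candidate threshold $t$ (the sorted observed p-values), the
estimated FDR is

$$\widehat{\mathrm{FDR}}(t) =
  \frac{\mathrm{median}_s\, \#\{p^{null}_s \le t\}}
       {\max(1, \#\{p^{obs} \le t\})},$$

capped at 1, and made monotone non-decreasing in $t$ by a running
maximum. The chosen threshold is the largest $t$ with adjusted estimate
at or below the target rate (default 1%); when none qualifies the
smallest observed p-value is reported with zero discoveries. The median
across simulations (rather than the mean) is the default numerator
summary for robustness; both are exposed, as is a parametric Gaussian
null option. Because every feature contributes to the numerator while
only true nulls generate false discoveries, the estimate is mildly
conservative by the factor $1/\pi_0$; at the default 10% non-null
mixture this is within the Monte-Carlo tolerance of the calibration
study. The default number of simulations at study scale is 2500;
desk-scale analyses and the test suite use 200–500, and the calibration
study in `scripts/acceptance.R` uses 300 per replicate.

## Enrichment

Enrichment of an annotation (e.g. "novel" features) within a model
class is tested by permutation of the age-category labels with full
re-classification per permutation, as the class assignment — not the
annotation — is the random object under the null of no age structure.
The statistic is the count of annotated genes in the target class
(default) or the annotated fraction of the class; the p-value is
tie-inclusive with the add-one correction, so it is valid (never
anti-conservative) and bounded below by $1/(B+1)$. Note the test is
sharp only against the joint null: with real expression structure but
annotation assigned independently, the observed class occupancy exceeds
the permuted occupancies and the count statistic is stochastically
large. The uniformity diagnostic in the test suite therefore uses
all-null expression, where full exchangeability holds, and the fraction
statistic, whose richer support keeps the discrete permutation
distribution close to continuous (the count statistic's ties make the
p-value visibly super-uniform at test sample sizes).

## Scan merging

The two laser-power scans are merged per channel at the intensity
level. A least-absolute-deviations line (fitted by iteratively
reweighted least squares — a two-parameter robust fit; no dedicated LAD
routine is needed) maps background-subtracted low-scan intensities onto
the high-scan scale, using only features unsaturated (saturated-pixel
fraction < 0.20, the same constant as the downstream saturation filter)
and above background in both scans, with at least 10 support features
required. Features saturated in the high scan are replaced by their
calibrated low-scan values; all others keep the high-scan measurement,
which has the better signal-to-noise ratio when read noise is constant
in absolute intensity units. QC fields travel with the scan actually
used, and a `source_scan` column records provenance. The merge is
idempotent and order-preserving in the substituted stratum.

## Normalization and assembly

M-values are recentred by a LOWESS fit of M on A via `stats::lowess`
(tricube weights, 3 robustness iterations), span 0.4 by default — the
common MA-normalization compromise between bias and variance; at least
30 usable features are required per array. The fit is equivariant under
adding a constant to all M-values, so the normalization is invariant to
global dye imbalance. Across arrays, a gene is retained when it passes
the four feature filters on at least 70% of arrays (the presence rule;
the threshold deliberately mirrors the pixel-filter constant and is
configurable), and per-array failures of retained genes stay missing —
all downstream fits tolerate missing values per gene.

## TaqMan screen

Reference normalization subtracts the arithmetic mean Ct of RNU44,
RNU48 and U6 per pool — exactly the geometric mean of the reference
abundances on the linear $2^{-Ct}$ scale. Assays without robust
expression (raw Ct > 29 at *every* timepoint) and passenger-strand
assays are dropped. Fold changes are plain $2^{-\Delta\Delta Ct}$
against a reference timepoint (no amplification-efficiency correction,
matching single-replicate pooled designs); censored reactions (Ct 40)
propagate as flags, never as point estimates, because pools have no
replicate variance to absorb censoring. The outlier screen pools log2
fold changes across all assays and non-reference timepoints and flags
entries beyond k = 2 SD of the pooled mean; the log2 scale makes
increases and decreases symmetric (a linear-scale option exists, as
does a per-timepoint variant of the pooling — the pooled-log2 default is
the natural choice when a single global fold-change distribution is the
reference). Epoch comparisons average log2 relative quantities within
each epoch's pools before exponentiating.

# The synthetic-data generator

The generator emulates the study conditions: 36 fetal / 9 young / 2
adult arrays by default (gestational weeks uniform on 14–24, postnatal
days up to 300, pools shared by developmental age); about 35% of
features "novel"; 90% of features flat with the remaining 10% spread
evenly over the 12 directional classes; adjacent unequal means
separated by `effect_size` = 1.5 log2 units over `noise_sd` = 0.25 —
a separation of 6 noise SD, the regime in which pattern recovery is
essentially complete and the calibration study is informative.
Intensities are built from a fixed per-feature reference-pool value
(log-uniform; novel features drawn bright so they saturate at full
power), a smooth intensity-dependent dye bias (amplitude 0.3 log2)
that LOWESS must remove, per-scan additive read noise of constant
absolute magnitude (so the 100% scan is gain-fold more precise until it
clips at 65535), and multiplicative gain noise. QC columns are drawn so
configurable fractions fail each filter. TaqMan Ct values are baseline
minus true log2 relative abundance plus cycle noise, censored at 40,
with near-constant reference assays and configurable fractions of
low-expressed and passenger-strand assays.

What the generator does *not* emulate: pixel-level image structure, dye
chemistry, spatial artefacts, RNA degradation or post-mortem-interval
effects, correlated gene-gene noise, and within-category developmental
gradients (category means are constant within an epoch). Passing tests
therefore demonstrate the statistical machinery under its working
assumptions, not robustness to every artefact of real arrays — the
residual-diagnostics report (`residualDiagnostics()`) exists precisely
to check those assumptions on real data.

# Numerical choices and degenerate inputs

* Background-subtracted intensities are floored at 1 before logs.
* Zero residual variance: omnibus p is 0 if the between-group sum of
  squares is positive (at tolerance $10^{-12}$ relative to the data
  scale), else 1; the fit is flagged.
* Correlation distances use pairwise-complete observations; pairs
  sharing fewer than 3 samples get the maximal distance 2 with a
  warning; zero-variance rows are rejected.
* `hclust` merges equal-height candidates by original index, so leaf
  orders are reproducible; average linkage is the default (the linkage
  is not dictated by the analysis and is configurable), Pearson the
  default correlation (Spearman via `method`).
* Permutations are sampled with replacement; designs with fewer
  distinct permutations than requested simulations warn.
* The single run seed fans out to deterministic per-stage child seeds,
  so stages re-run alone reproduce their in-pipeline results.

# Problem sizes used by the tests

The calibration study runs 50 replicates of 2000 genes × 36 samples
with 300 null permutations each; the oracle-equivalence check uses
10,000 random small instances (2–10 samples per group); uniformity
diagnostics pool 10,000 permutation-null p-values and 60 repeated
enrichment experiments of 3000 null genes each. These sizes give the
Monte-Carlo error targeted by the assertions (about half a percentage
point on a realized FDR of 1%) while keeping a full test run in the
minutes range.

# Known limitations

* Only the three-category design is implemented and tested; the
  machinery generalizes conceptually but not in code.
* The protected backward selection reports at most one merge for a
  significant gene by construction; patterns with two equalities and a
  significant omnibus test cannot arise.
* The enrichment permutation re-classifies per permutation and is
  correspondingly costly; the annotation-permutation cross-check is the
  cheap alternative under independence.
* Censored TaqMan fold changes are flagged bounds; no likelihood-based
  censoring model is attempted for single-replicate pools.
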