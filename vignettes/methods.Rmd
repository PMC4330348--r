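---
title: "Methods: network analysis of mixed-reference peptide-pulldown data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network analysis of mixed-reference peptide-pulldown data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices made where the method was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The measurement model

A peptide-capture experiment compares the binding of nuclear proteins
to nine conditions: eight histone H3 tail peptides carrying defined
methyl/phospho modifications and a beads-only negative control, each in
two replicates. Quantification uses a pooled mixed reference: the
light-labelled eluates of all nine pulldowns of a replicate are pooled
and split into nine equal aliquots, one spiked into each heavy pulldown.
The H/L ratio of protein $i$ in condition $c$, replicate $r$, is

$$\mathrm{HL}_{icr} = \frac{h_{icr}}{\tfrac{1}{9}\sum_{c'} \ell_{ic'r}}$$

where $h$ and $\ell$ are heavy and light bound amounts. Two properties
follow and anchor the tests: the nine ratios of a fully observed
protein sum to 9 when heavy and light captures agree, and a protein
bound in a single condition scores 9 there and 0 elsewhere.

## The synthetic world

The generator (`simulate_dataset()`) is a stated world, not a fitting
device:

* **Planted complexes.** Each complex is a set of proteins sharing one
  nonnegative affinity vector over the nine conditions ("a complex
  binds as a unit"), scaled by a per-complex abundance. The default
  library (`make_signature_library()`) carries eight archetypes whose
  qualitative contrasts mirror well-described reader classes: an
  HP1-like K9me3 reader almost fully displaced by S10 phosphorylation
  (double-mark affinity < 10% of K9me3), an Atrx-like reader binding
  K9me3 and K9me3/S10ph within 20% of each other, a 14-3-3-like reader
  preferring S28ph over S10ph by several fold, a NuRD-like binder
  highest on the unmodified 1–20 peptide and lowest on the double mark,
  a SWI/SNF-like binder of unmodified and K9me3 tails displaced by
  S10ph, a PRC2-like reader with exactly 3-fold higher K9me3 than
  K27me3 affinity, and two further classes (a phospho-tolerant broad
  K9me3 binder, a generic tail binder). Within those constraints the
  numeric values were chosen once so the archetypes are mutually
  distinguishable (maximum pairwise signature correlation ≈ 0.75):
  planted truth is only a usable ground truth if the planted classes
  are separable in principle. Sizes span 5–60 members — the minimum
  module size up to a large complex — among 300 flat background
  proteins.
* **Noise** is multiplicative lognormal with a coefficient of variation
  `noise_cv` (default 0.2), drawn independently per protein ×
  condition × replicate and independently for the heavy and light
  captures. Ratio data are strictly positive and right-skewed, which a
  CV-parameterized lognormal reproduces; 0.2 is a typical
  replicate-to-replicate spread for affinity-enrichment SILAC and is a
  free parameter of the world (the source study does not state one).
* **Missingness** is abundance-dependent, not completely at random: an
  entry is retained with probability
  $\mathrm{logit}^{-1}\!\big(s\,(\log b - m)\big)$ on its true bound
  amount $b$ (slope $s = 1.5$ by default). This mirrors
  mass-spectrometric detection limits and makes the pipeline's zero
  imputation consequential: dropped entries are mostly low-signal, so
  imputed zeros approximate truth for complex members and preserve
  their mutual correlation. The midpoint $m$ can be calibrated
  deterministically to a target overall missingness
  (`target_missing_rate`, 30% in the validation scenario).
* **Beads binding** is a small constant (0.05) added to every
  condition, so the negative control has signal and the enrichment
  statistics are exercised.
* The full dataset is bit-reproducible from its seed.

What a green recovery test does establish: the network pipeline
separates co-binding complexes from uncorrelated background at 20%
noise and 30% structured missingness. What it does not: performance on
real data with correlated contaminants, shared peptides between protein
groups, batch structure between replicates, or abundance-dependent
ratio compression — none of which the generator emulates.

## Network construction

Correlation is computed on the zero-imputed matrix over all 18 columns
(replicates kept as independent samples; their concordance is itself
clustering signal). The signed soft-threshold adjacency
$a_{ij} = ((1+\mathrm{cor}_{ij})/2)^{\beta}$ with $\beta = 15$ maps
anticorrelation to 0 — appropriate because complex members co-bind —
and the classic topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \neq i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}$$

is applied to it (the adjacency is already nonnegative, so the unsigned
formula is well defined). `pick_soft_threshold()` reports the
scale-free fit index — the $R^2$ of a log–log regression of binned
connectivity frequency on mean connectivity, signed by the slope — for
candidate powers; the pipeline records the table and uses 15. The fit
uses ten equal-width connectivity bins: equal-occupancy bins would make
the frequency constant by construction and the regression degenerate.

## Module detection

Proteins are clustered by average linkage on $1-\mathrm{TOM}$. The cut
is a deterministic adaptive branch decomposition with parameters in
units of the maximum merge height $h_{\max}$:

1. a static cut at $0.99\,h_{\max}$ separates top-level branches;
2. a branch whose merge heights span more than $0.25\,h_{\max}$ is
   heterogeneous and splits into its children, recursively;
3. a homogeneous branch only coheres as a module if its top height is
   below $0.9\,h_{\max}$ — homogeneous-but-high branches are diffuse
   background and dissolve to grey (with a floor so that a tree with no
   height variation at all yields one module rather than none);
4. fragments smaller than the minimum module size (5) are offered for
   adoption to the candidate branch with the smallest mean TOM
   dissimilarity, accepted only within that branch's *original* mean
   internal dissimilarity plus the spread tolerance. Anchoring the
   radius to the original core — never widening it with adoptees —
   prevents adoption from snowballing into absorbing background;
5. surviving branches of size ≥ 5 become modules, named by colours in
   decreasing size order; everything else is grey.

The thresholds come from the observed height geometry of the planted
world: complex branches cohere below ≈ 0.7 $h_{\max}$ while
background-only branches only merge above ≈ 0.95 $h_{\max}$, so 0.9 is
a conservative separator, and 0.25 comfortably exceeds the within-branch
height jitter of a coherent module at the default noise. A common
alternative — splitting a branch when its top merge exceeds the mean of
its internal heights by a multiple of their spread — collapses on
realistic trees: at the root the internal spread of a mixed tree is so
large that no split ever fires. A plain static cut at a single height
is available as a fallback (`static_cut_height`).

The assignment is invariant under permutation of protein order, and on
the stated synthetic world recovers all eight planted complexes with
adjusted Rand index ≥ 0.8 in at least 18 of 20 seeds (the acceptance
suite measures this; parameters were frozen before evaluation on the
held-out seed range).

## Module characterization

The eigenprotein is the first right-singular vector of the module's
row-standardized profile matrix, with variance explained
$\sigma_1^2/\sum\sigma_k^2$. Rows are standardized so abundance scale
cannot dominate the component (the source convention; raw-ratio
eigenproteins are a one-line change but are not exposed). The sign is
oriented so the eigenprotein correlates positively with the module's
mean standardized profile, making binding-profile plots interpretable.
Intramodular connectivity sums a protein's adjacencies to same-module
partners and divides by the module maximum, so each module's top hub
scores exactly 1; hub ranking breaks ties by total connectivity, then
protein id, for determinism.

## Binding statistics

Enrichment works on the un-imputed matrix through the missingness mask:
per protein and condition, the mean over measured replicates is log2
transformed and the protein's beads-only value subtracted. The module
test is a classic paired two-tailed t on those per-protein differences.
The outlier z-score fixes the null mean at zero ("standard deviations
above zero"): $z_i = d_i/\sigma$ with $\sigma$ the sample standard
deviation of all defined $d$ in the pulldown; the default p-value is
the one-sided upper tail, because the statistic is defined in the
enrichment direction (a two-sided option exists). Whether protein $i$
should be excluded from its own $\sigma$ is not specified anywhere;
the default includes it (at cohort sizes of hundreds the difference is
negligible) and a leave-one-out flag is exposed. The module t-test runs
on the log2 scale for variance stabilization and symmetry with the
outlier analysis. p-values are reported raw by default, matching the
published convention; Benjamini–Hochberg adjustment is optional.

Degenerate cases carry flags rather than silent values: zero variance
with nonzero mean reports p = 0 with `degenerate_variance`; fewer than
two pairs reports `insufficient_pairs`; a zero-σ condition yields NA
z-scores.

## IP networks

Co-IP H/L ratios are divided by the bait's own pulldown ratio, making
edge weights invariant to overall IP efficiency. Reciprocal detections
merge into one undirected edge keeping the larger weight (the stronger
detection) with both weights preserved under a reciprocal flag. Preys
under two ratio counts are dropped, as is the bait self-edge. Exports:
TSV edge/node tables at full precision and GraphML with module and
kWithin attributes.

## Numerical choices and degenerate inputs

* Constant protein rows (correlation undefined) are removed with a
  warning before networking.
* Average linkage is monotone, but exact ties can leave
  floating-point-level height inversions; heights are monotonized by
  cumulative maximum (tolerance 1e-8) before cutting.
* True zeros can arise in the noiseless generator corner (a protein
  absent from a condition); at ingest, parsed zeros are treated as
  missing because real H/L ratios are strictly positive.
* All randomness flows from explicit integer seeds; simulate-mode runs
  are bit-reproducible and the run manifest records config, versions
  and seed.

## Known limitations

* The module catalogue of any real dataset depends on tree-cut
  parameters; exact reproduction of a specific published catalogue is
  not claimed and would require the original raw-spectra processing.
* The generator does not model protein-group inference, shared
  peptides, label-swap designs, 3-plex SILAC, or batch effects.
* The scale-free fit index is descriptive; the pipeline does not select
  β automatically.
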