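# silacnet

Weighted correlation network analysis of super-SILAC peptide-pulldown
proteomics.

## The problem

Histone-tail "reader" proteins bind post-translational modifications on
histone H3 — often as pre-assembled complexes whose members share a
common binding profile across modified peptides. A peptide-capture assay
measures this: nuclear extract is incubated with immobilized synthetic
H3 tail peptides (unmodified, K9me3, S10ph, K9me3/S10ph, K27me3, S28ph,
K27me3/S28ph, plus a beads-only control), and each captured proteome is
quantified by SILAC against a *pooled mixed reference* — the light-label
eluates of all nine pulldowns pooled and split into nine equal aliquots.
The heavy/light (H/L) ratio of a protein in a pulldown is then its
enrichment over the common reference, which makes all nine conditions
directly comparable; for a protein measured in all nine conditions the
H/L ratios sum to 9 by construction.

`silacnet` is the analysis side of that design, for proteomicists with a
protein-groups ratio table in hand: it finds groups of proteins with
near-identical binding signatures (candidate reader complexes), scores
their binding against the beads control, and assembles bait-normalized
co-IP validation networks. A seeded synthetic-data generator plants
complexes with known signatures so every stage can be validated against
ground truth.

## The method

Given a proteins × 18 samples matrix of H/L ratios (9 conditions × 2
replicates), after contaminant/decoy removal, a ≥ 2 ratio-count rule per
measurement, and a missingness filter (keep proteins quantified in ≥ 4
of 18 samples; i.e. at most 14 missing), remaining missing values are
imputed to zero and:

1. **Signed weighted network** — pairwise Pearson correlation `cor_ij`
   over the 18 samples; adjacency `a_ij = ((1 + cor_ij)/2)^β` with soft
   power `β = 15`, keeping only positive co-binding relationships and
   yielding approximately scale-free connectivity.
2. **Topological overlap** —
   `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)` with
   `l_ij = Σ_u a_iu a_uj`, a shared-neighbourhood similarity robust to
   single noisy edges.
3. **Modules** — average-linkage clustering of `1 − TOM`, cut by a
   deterministic adaptive tree cut (minimum module size 5; unassignable
   proteins pooled as "grey"; modules named by colours in decreasing
   size order).
4. **Module summaries** — the eigenprotein (first principal component of
   the module's standardized profiles) and intramodular connectivity
   kWithin, normalized so each module's top hub scores exactly 1.
5. **Binding statistics** — per condition, replicate-mean H/L ratios
   (missing values ignored), log2, beads value subtracted; a paired
   two-tailed t-test per module × condition against the beads control,
   and per-protein outlier z-scores `z = d/σ` (null mean 0, σ the
   within-pulldown standard deviation) with normal-tail p-values.
6. **IP networks** — reciprocal SILAC co-IP ratios normalized by the
   bait's own pulldown ratio, merged into an undirected weighted network
   (reciprocal detections flagged, max weight kept), exported as
   TSV/GraphML with kWithin node attributes.

## Worked example

```r
library(silacnet)

cfg <- pipeline_config(list(
  mode = "simulate", seed = 11, output_dir = "results",
  generator = list(n_background = 300, noise_cv = 0.2,
                   target_missing_rate = 0.3)))
bundle <- run_pipeline(cfg)
#> [silacnet] simulate: 480 proteins, 2586 missing entries
#> [silacnet] missingness filter: 480 -> 478 proteins (max 14 missing)
#> [silacnet] modules: 8 modules, 296 grey proteins

module_sizes(bundle$assignment)
#> turquoise      blue     brown    yellow     green       red     black      pink
#>        60        40        30        21        13         7         6         5
```

The simulated world plants eight reader-complex archetypes (an HP1-like
K9me3 reader, a NuRD-like unmodified-tail binder, a SWI/SNF-like
unmod/K9me3 binder, an Atrx-like phospho-methyl switch reader, a
14-3-3-like S28ph reader, a PRC2-like reader, and two smaller classes)
among 300 flat background proteins, at 20% measurement noise and 30%
missingness. The eight recovered modules are exactly the eight planted
complexes (adjusted Rand index 0.994 against planted truth on this
seed); the top hub of each module is a member of its planted complex:

```r
head(bundle$hubs[bundle$hubs$rank == 1, c("module", "protein", "kWithin")])
#>       module        protein kWithin
#>        black    prc2_like_4       1
#>         blue   nurd_like_39       1
#>        brown swisnf_like_28       1
#>        green    atrx_like_1       1
#>         pink   bnhej_like_4       1
#>          red    p1433_like_6       1
```

The module-versus-beads paired t-tests rank the expected contrasts on
top — the HP1-like module ("turquoise") on the K9me3 peptide, the
NuRD-like module ("blue") on the unmodified tails:

```r
head(bundle$module_tests[order(bundle$module_tests$p_value), ], 3)
#>       module     condition t_statistic df  p_value n_pairs
#>    turquoise       H3K9me3       136.1 59 2.06e-75      60
#>         blue H3_1-20_unmod       105.0 39 1.86e-49      40
#>         blue H3_18-38_und        76.0 39 5.28e-44      40
```

All outputs (filtered matrix, module labels, eigenproteins,
connectivity, hub list, enrichment and outlier tables, JSON manifest)
are written as TSVs to `output_dir`.

A command-line wrapper with `simulate`, `run`, `stats` and
`export-network` subcommands is installed at
`system.file("exec", "silacnet", package = "silacnet")`.

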