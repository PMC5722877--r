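---
title: "Linking drought-response transcriptomes to tree co-occurrence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking drought-response transcriptomes to tree co-occurrence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drydisp)
```

## The question and the statistical chain

`drydisp` implements a community-transcriptomics workflow that asks whether
tree species with similar transcriptomic responses to experimental drought
co-occur non-randomly in a mapped forest stand, and whether that
co-occurrence concentrates on dry soils. The chain is:

1. **Gene set enrichment per species.** Each species contributes a table of
   genes with a log2 fold change (drought vs. control), a p-value, and GO
   annotations. Genes are called differentially expressed (DE) when
   `|log2FC| >= 1` and the Benjamini–Hochberg adjusted p-value is below
   0.05; the direction of change is ignored, since both up- and
   down-regulation are informative about responsiveness. Because each
   species has its own de novo reference, genes are compared through shared
   GO terms rather than orthologs: only terms annotated in **every**
   species enter the analysis. For each (species, term) a one-sided
   Fisher's exact test asks whether DE genes are over-represented in the
   term's gene set, and p-values are Benjamini–Yekutieli corrected across
   the universe within each species (BY is valid under the arbitrary
   dependence created by overlapping gene sets).
2. **Species dissimilarity.** Species are hierarchically clustered
   (average linkage) on their binary significance profiles; the cophenetic
   path length through the dendrogram (twice the merge height) is the
   expression dissimilarity `delta`. Parallel `delta` matrices come from
   the odds-ratio dendrogram (Euclidean on log2 OR), the first two
   principal-component axes of eight functional traits, patristic
   distances on the phylogeny, absolute differences in days-to-wilting and
   in each environmental tolerance, and — per individual GO term — the 0/1
   indicator of discordant enrichment states.
3. **Dispersion.** For every 20 × 20 m subplot the abundance-weighted mean
   pairwise distance
   $\mathrm{MPD} = \sum_i \sum_j \delta_{ij} f_i f_j \big/ \sum_i \sum_j f_i f_j$
   is compared with a taxa-label null (999 relabelings of the distance
   matrix over the full species pool) and standardized:
   $\mathrm{S.E.S.} = (\mathrm{MPD}_{obs} - \overline{\mathrm{MPD}}_{null}) / \mathrm{sd}(\mathrm{MPD}_{null})$.
   Negative values mean co-occurring species are more similar than chance.
4. **Space.** Soil volumetric water content (vwc), measured on a nested
   40-m core design, is kriged to the subplot grid from a weighted
   least-squares variogram fit. S.E.S. maps are Pearson-correlated with
   moisture (point mode: core-bearing subplots only; kriged mode: all
   subplots) and significance comes from an exhaustive torus translation,
   which preserves each map's internal spatial autocorrelation.
5. **Phylogenetic signal.** A Mantel test relates patristic distance to
   expression dissimilarity; per-GO binary enrichment states are scored
   with the Fritz–Purvis D statistic.

## Conspecific pairs in MPD

The unrestricted double sum includes `i = j` terms, whose zero distances
deflate MPD in monodominant subplots. The default excludes conspecific
pairs, matching the standard abundance-weighted MPD whose interpretation
("co-occurring *species* more similar than expected") the workflow relies
on; `include_conspecific = TRUE` evaluates the literal unrestricted sum
(this is also what `picante`'s abundance-weighted MPD computes, which the
test suite uses as a cross-check). The taxa-label null permutes the full
pool's labels once per iteration, shared across subplots: each subplot's
marginal null is identical to per-subplot permutation, and sharing makes
the 630-subplot map computable as one matrix product per iteration.

## The synthetic study system

No raw study data ship with the package; a generator produces complete
datasets with known ground truth so every stage is testable end to end.
Its defaults are fixed to the study conditions:

* **Geometry:** 630 subplots of 20 × 20 m (25.2 ha). The plot's aspect
  ratio is not published, so the grid is taken as 35 × 18 (700 × 360 m) —
  a modeling choice, as is the 40-m soil lattice convention (interior
  nodes at 40, 80, … m; satellites at 2, 8 and 20 m from every other node
  in one uniform random direction, resampled to stay in bounds).
* **Moisture field:** Gaussian random field with an exponential
  (practical-range) covariance, range 100 m, sill 1, nugget 0.1, min–max
  rescaled to [0, 1] vwc units.
* **Guilds:** 3 drought-response guilds with moisture optima evenly spread
  across the field's range, Gaussian niches (`niche_sd = 0.25` vwc), and
  multiplicative habitat filtering `filter_strength = 0.5`; subplot
  abundances are Poisson with mean 4 stems per species per subplot
  (~84 stems/subplot, ~53k stems — a realistic temperate-plot census).
  `filter_strength = 0` yields an exchangeable, neutral community.
* **Transcriptomes:** 3000 genes per species over a shared universe of
  59 BP + 45 MF terms (the size of the study's cross-species universe).
  Each guild "activates" 20% of terms per namespace (disjoint across
  guilds); genes annotated to an active term are DE with probability 0.5
  vs. 0.05 background. DE p-values are drawn directly
  (`10^-U(3,10)`); a count model is deliberately out of scope since
  enrichment consumes only (log2FC, p).
* **Response coherence declines toward mesic guilds**
  (`coherence_gradient = 0.4`): a species keeps fraction
  `1 - 0.4 * optimum` of its guild's shared active set and swaps the rest
  for idiosyncratic terms. This encodes stress-gradient filtering — on
  harsh (xeric) sites the coordinated drought response is what permits
  residency, while mesic assemblages are not filtered on that axis — and
  it is what gives the moisture–S.E.S. correlation its observed sign:
  co-occurring species are most non-randomly similar on dry soils, so
  S.E.S. *rises* with water content. A fully symmetric guild model makes
  both ends of the gradient equally clustered and produces no correlation.
* **Covariates:** eight traits mix a guild mean with noise at weight 0.4;
  days-to-wilting and drought tolerance follow the dryness of the guild
  optimum at weight 0.5; shade and water-logging tolerances are
  over-dispersed within guilds (each guild spans the full range on an even
  lattice), reproducing the positive-S.E.S. pattern expected when
  co-occurring species diverge on competition axes. The coupling ordering
  (expression strongest, then wilting, then traits, phylogeny uncoupled)
  is itself a study condition: it is what makes expression the best
  predictor of co-occurrence, and the acceptance suite verifies the
  resulting S.E.S. ordering rather than assuming it.

What the generator does **not** emulate: read-level data, assembly or
annotation error, GO-graph structure (term overlap is random, not
hierarchical), stem-level coordinates below subplot grain, demographic or
temporal dynamics, and spatial aggregation of conspecifics beyond what
moisture filtering induces. Passing tests therefore validate the
statistical machinery and its calibration under a plausible assembly
model — not the biological claims of any particular field system.

## Numerical and design choices

* **Fisher sidedness:** one-sided over-representation (`phyper` upper
  tail), with a two-sided option; the choice is not material to the
  ranking analyses, which use the BY-significant indicator.
* **Odds ratios:** sample OR `ad/bc` with Haldane–Anscombe +0.5 on all
  cells when any cell is zero, keeping the clustered values finite.
* **Gene universe per species:** all genes in the table, annotated or not
  (configurable).
* **Linkage and metrics:** average linkage by default; Euclidean on
  log2 OR for odds-ratio profiles; Euclidean on 0/1 for significance
  profiles (same ordering as squared Jaccard here), both configurable.
  Rows are sorted by species label before clustering so ties break
  deterministically.
* **Cophenetic convention:** tip-to-tip path (2 × merge height) by
  default; merge height alone is available and only rescales `delta`,
  leaving S.E.S. unchanged in rank.
* **Kriging:** ordinary kriging in semivariance form with a Lagrange
  multiplier; weights sum to 1 by construction and prediction is exact at
  cores when the nugget is 0. Variograms (spherical or exponential,
  practical-range parameterisation) are fit by weighted least squares
  (weights `n_pairs / lag^2`) with a deterministic multi-start grid;
  12 bins to half the maximum pairwise distance.
* **Torus translation:** exhaustive cyclic shifts at the 20-m subplot
  grain (nx × ny shifts; reflections optional), two-sided p on `|r|` by
  default, pairwise-complete correlation with missing cells travelling
  with their map. The identity shift is part of the null, so
  `p >= 1/n_shifts`.
* **D statistic:** nodal values by the branch-length-weighted
  (contrasts-style) down-pass, d = sum of sister-clade differences;
  random anchor from tip shuffles, Brownian anchor from thresholded
  Brownian simulations at the observed prevalence. The original
  convention (Brownian 0, random 1) is the default; a shifted
  `as_printed` convention anchoring Brownian at 1 is reported alongside,
  since both conventions circulate. p-values are add-one smoothed
  permutation proportions (clumping-sided by default).
* **Degenerate cases:** subplots with fewer than two species, zero null
  standard deviations, monomorphic GO columns and constant traits yield
  missing values (never exceptions) and are excluded from means and
  correlations, never imputed.

## Null calibration and its edge case

Under an exchangeable community (`filter_strength = 0`) the S.E.S. maps
are well calibrated: mean ≈ 0, sd ≈ 1, and for continuous dissimilarities
(trait PC axes, patristic distances) the fraction of subplots below −1.96
sits near 2.5%. One caveat is intrinsic to the statistic: the expression
dendrogram's cophenetic matrix is strongly clustered (a few distinct
values arranged in guild blocks), which makes the per-subplot null MPD
distribution left-skewed; its standardized lower tail then holds ~5%
rather than 2.5%, with an empty upper tail. This is a property of MPD on
clustered distance matrices, not of the permutation machinery, and it is
why per-GO rankings compare mean S.E.S. values rather than tail counts.

## Problem sizes

The test and acceptance runs use the full study geometry (630 subplots,
21 species, 104-term universe) with 999 null permutations for the
dispersion analyses, 999 permutations/simulations for Mantel and the
D-statistic anchors, and 1500–3000 genes per species; enumeration oracles
(hypergeometric tails, 3-species label permutations, 2 × 2 torus grids,
5-species Mantel) pin the exact components. A full pipeline run at these
sizes completes in well under a minute on one CPU.
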