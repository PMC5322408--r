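# depthcline

Delineating cryptic, sympatric fish species along a lacustrine
spawning-depth gradient, from multi-mesh gill-net surveys and microsatellite
genotypes.

## The problem

Postglacial whitefish radiations in deep subalpine lakes often hold more
species than fisheries managers recognise: sibling species differing in
growth rate, gill-raker counts and spawning depth can intermingle on the
same winter spawning grounds, and survey gear itself distorts the size
distributions used to tell them apart. `depthcline` packages the complete
analytical chain needed to delineate such species from a depth-stratified
gill-net survey:

1. **Gear-selectivity correction** — per-mesh catch-at-length is fitted with
   right-skewed normal retention curves (location ξ, scale ω, shape α ≥ 0);
   the curves are rescaled to unit maximum, summed into a total-selectivity
   curve, and the standard lengths where adjacent mesh curves cross define
   selectivity SL classes to which every fish is assigned irrespective of
   its capture mesh.
2. **Growth-cluster delineation** — Shapiro–Wilk screening of SL-at-age
   distributions; 1–3 component Gaussian mixtures compared by
   AICc = −2 lnL + 2p + 2p(p+1)/(n−p−1) with p = 3k−1; and a dynamic hybrid
   tree cut (average-linkage dendrogram, minimum cluster size 10 % of n,
   detect-then-attach) that estimates the number of growth clusters without
   prespecifying k.
3. **Population genetics** — Weir–Cockerham θ (ratio of variance-component
   sums over loci and alleles) with permutation tests and
   Benjamini–Hochberg FDR; one-level AMOVA under alternative groupings
   (capture date, depth, mesh, SL class); observed/unbiased expected
   heterozygosity and F_IS; Hardy–Weinberg exact tests (Levene enumeration
   for biallelic loci, Monte-Carlo otherwise); pairwise linkage-equilibrium
   G tests; ADZE-style rarefied allelic richness and (generalized) private
   allelic richness E[A] = Σᵢ (1 − C(N−Nᵢ, g)/C(N, g)); Cavalli-Sforza
   chord distances with neighbour-joining trees and locus-bootstrap support;
   Smouse–Peakall individual genetic distances.
4. **Isolation-by-adaptation tests** — Mantel and residual-permutation
   partial Mantel correlations of individual genetic distance with
   standard-length, gill-raker and capture-depth differences, against
   haversine geographic distance for isolation-by-distance; DAPC-style
   assignment (PCA of allele counts, PC count chosen by cross-validated
   assignment RMSE, linear discriminant posteriors).
5. **A synthetic survey generator** — Balding–Nichols species pools (star or
   stepping-stone clinal divergence), per-species phenotype models, and a
   gill-net survey simulator with known selectivity truth, so every stage is
   testable end-to-end. The `lucerne3` preset emulates a three-species
   alpine gradient (trimodal SL at age 3: 200/275/350 mm; gill-raker means
   37.8/33.3/27.7; spawning depths 32/18/6 m; clinal F_ST ≈ 0.045–0.09).

All user-facing functions take a data frame (or the package's
`genotype_tbl`) first and return tibbles, so stages compose with the pipe;
results carry `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

```r
library(depthcline)

cfg <- default_config()
cfg$preset <- "lucerne3"
cfg$seed <- 42L
cfg$fst_permutations <- 999L   # desk-scale; default is 10,000
report <- run_pipeline(cfg)
summary(report)
```

The run above prints (seed 42, desk-scale F_ST permutations):

```
# A tibble: 1 × 12
  k_clusters k_mixture fst_min fst_max all_fst_significant  phi_date phi_depth
       <int>     <int>   <dbl>   <dbl> <lgl>                   <dbl>     <dbl>
1          3         3  0.0379  0.0661 TRUE                -0.000251   0.00925
  phi_mesh phi_sl_class mantel_r_sl mantel_r_gr mantel_r_depth
     <dbl>        <dbl>       <dbl>       <dbl>          <dbl>
1   0.0426       0.0490       0.198      0.0702         0.0379
```

Reading it: the survey resolves **three growth clusters** (both by AICc and
by tree cut); grouping fish by SL cluster explains the most genetic variance
(Φ_ST = 0.049, versus 0.043 by mesh, 0.009 by depth and ~0 by capture
date); every pairwise F_ST (0.038–0.066) stays significant after FDR; and
individual genetic distance correlates most with standard length, then
gill-raker count, then capture depth — the isolation-by-adaptation
signature. `write_report(report, "outdir")` writes every stage table as CSV
plus a JSON provenance record, and `autoplot()` on the selectivity model,
cluster solution or F_ST matrix draws the standard figures.

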