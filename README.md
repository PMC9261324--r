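# coexAge

Weighted co-expression modules, hub genes and age trajectories in
two-cohort transcriptomes.

## The problem

Bulk PBMC (peripheral blood mononuclear cell) expression changes with age,
but not uniformly: groups of co-regulated genes move together, some
gradually, some abruptly at particular ages, and only part of the signal is
shared between ancestry groups. The standard analysis route is weighted
gene co-expression network analysis (WGCNA): build a signed-strength
network from gene–gene correlations, cluster it into modules, summarize
each module by its eigengene, and correlate eigengenes with traits such as
age and sex. Downstream, differentially expressed genes are intersected
with the interesting modules, hub genes are ranked on a protein–protein
interaction (PPI) subnetwork, gene-set over-representation annotates module
function, and the age-related gene sets of two cohorts are intersected to
extract a shared aging signature.

`coexAge` re-implements that whole route as tested, reusable R functions,
and ships a synthetic two-cohort generator with planted ground truth
(age-correlated modules, a cross-cohort shared module, hub genes embedded
in dense cliques) so every stage can be validated without any external
download.

## The statistics at the core

* **Soft-thresholded adjacency** `a_ij = |cor(x_i, x_j)|^β` (or
  `((1+r)/2)^β` signed), with β chosen as the smallest power whose
  scale-free topology fit reaches R² > 0.8 with negative slope.
* **Topological overlap** `TOM_ij = (l_ij + a_ij) / (min(k_i,k_j) + 1 − a_ij)`
  with `l_ij = Σ_u a_iu a_uj`; genes are clustered by average linkage on
  `1 − TOM` and the tree is cut statically; modules with eigengene
  correlation ≥ 0.8 (cutline 0.2) are merged.
* **Module eigengene**: first principal component of the module's
  standardized expression, unit variance, oriented along the module mean;
  module–trait association by Pearson r with p from
  `t = r√(n−2)/√(1−r²)`.
* **Differential expression**: Welch t or an empirical-Bayes moderated t
  (method-of-moments variance shrinkage), Benjamini–Hochberg control, DEG
  calls at `|logFC| ≥ 0.5` and adjusted `p < 0.05`.
* **Hub ranking**: maximal clique centrality
  `MCC(v) = Σ_{C ∈ S(v)} (|C|−1)!` over the maximal cliques containing
  `v` (Bron–Kerbosch enumeration), top-k reporting with deterministic
  tie-breaks.
* **Over-representation**: upper-tail hypergeometric test of a query gene
  list against GMT gene sets within a measured universe, BH-corrected per
  collection, significance at adjusted `p` below the cutoff **and** overlap
  count strictly above 6.
* **Age trajectories**: continuous piecewise-linear least squares with 0–2
  grid-searched breakpoints selected by BIC; Wilcoxon rank-sum contrasts of
  PC1 scores; `2^-ΔΔCt` relative expression for qPCR-style validation.

## Worked example

```r
library(coexAge)

sim <- simulateCohort(
    nBackground = 300,
    modules = list(
        moduleSpec("rising", 60, ageEffect = ageEffectLinear(0.05), nHubs = 1),
        moduleSpec("stable", 60, nHubs = 1)),
    nSamples = 60, seed = 42)

net <- discoverModules(sim$expr, beta = 6)
moduleSizes(net$partition)
#>      blue turquoise
#>        60        60

traits <- truthTraits(sim$truth)
subset(moduleTraitCorrelation(net$eigengenes, traits, which = "age"))
#>      module trait      r        p
#> 2 turquoise   age  0.956 1.23e-32
#> 1      blue   age -0.119 3.66e-01
```

Both planted modules are recovered exactly (300 background genes stay
unassigned); the turquoise eigengene tracks age (r = 0.956) and the other
module does not. The age-related module's trajectory is linear, so the
breakpoint search keeps the 0-break model:

```r
ag  <- ageRelatedGenes(net, traits)
fitTrajectory(eigengenes(net$eigengenes)[ag$modules[1], ], traits$age)
#> Piecewise-linear age trajectory: 0 breakpoint(s)
#>   segment slopes: 0.0442
#>   BIC by breakpoint count: 0=-140.3 1=-134.4 2=-134.9
```

Differential expression between the young (≤ 40) and old (≥ 65) sample
groups recovers the rising module, and MCC ranks the planted hubs first:

```r
keep <- traits$group %in% c("young", "old")
m    <- SummarizedExperiment::assay(sim$expr)[, keep]
tab  <- selectDegs(logFoldChange(m, traits$group[keep]),
                   degTest(m, traits$group[keep], method = "moderated")$p)
attr(tab, "summary")
#>    nUp  nDown nTotal
#>     61      2     63
intersectWithModule(tab, net$partition, ag$modules[1])$venn
#>    degOnly    overlap moduleOnly
#>          3         60          0

g <- simulatePPI(sim$truth, seed = 42)
head(mccScores(g), 3)
#>                    gene mcc log10Mcc degree
#> stable_g001 stable_g001 256 2.408240     21
#> rising_g001 rising_g001 246 2.390935     16
#> rising_g026 rising_g026 137 2.136721     19
```

`stable_g001` and `rising_g001` are exactly the planted hub genes: each
sits in two planted 6-cliques (2 × 5! = 240) plus a few background cliques,
while ordinary clique members score about half that.

For two-cohort analyses, `simulateTwoCohorts()` plants a shared module in
both cohorts, `discoverModules()` + `ageRelatedGenes()` run per cohort, and
`sharedSignature()` intersects the age-related gene sets and scores the
overlap by a hypergeometric tail. `runOra()` annotates any gene list
against user-supplied GMT collections.

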