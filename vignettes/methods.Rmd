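---
title: "Models and methods behind coexAge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coexAge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coexAge` implements a differential co-expression workflow for aging
transcriptomes: co-expression module discovery, module–trait correlation,
differential expression, clique-centrality hub ranking, gene-set
over-representation, age-trajectory breakpoint detection, and cross-cohort
shared-signature extraction, together with a ground-truth cohort
simulator. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic experiments do and do not
establish.

## The co-expression network model

Let $X$ be a genes × samples matrix on a log-like scale. The network
stage computes the Pearson correlation matrix $R$, raises it to a soft
threshold — unsigned $a_{ij} = |r_{ij}|^\beta$ by default, signed
$a_{ij} = ((1+r_{ij})/2)^\beta$ on request — and converts adjacency into
topological overlap

$$\mathrm{TOM}_{ij} = \frac{l_{ij} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad
l_{ij} = \sum_{u \neq i,j} a_{iu} a_{uj}, \quad
k_i = \sum_{u \neq i} a_{iu},$$

so that two genes are similar when they are both directly connected and
share neighbors. Genes are clustered by average linkage on
$1 - \mathrm{TOM}$.

**Choice of β.** `pickSoftThreshold()` returns the smallest candidate
power whose scale-free topology fit exceeds the target (default $R^2 >
0.8$) with negative slope. The fit bins connectivities into ten
equal-width bins and regresses $\log_{10}$(bin frequency) on
$\log_{10}$(bin mean $k$). When no candidate qualifies — equal-sized
synthetic modules, for instance, give multimodal rather than right-skewed
connectivity — the best-fitting power is returned with a warning; the
recovery experiments in the test suite therefore fix β = 6, a
conventional power for unsigned bulk-expression networks, rather than
relying on the fallback.

**Assumptions.** At least 3 samples; no zero-variance genes (they are a
hard error, since their correlations are undefined); unsigned networks
treat anti-correlated genes as connected, which is the default here
because the sign convention of the emulated analyses is not fixed.

## Tree cutting and module merging

Dynamic tree cutting has many unstated degrees of freedom, so module
detection here is a *static* cut chosen for determinism and testability:
the dendrogram is cut at `min(h) + cutQuantile * (max(h) − min(h))` of
its merge-height span (default `cutQuantile = 0.95`). The cut is taken on
the height *span*, not on the height distribution: most merges are low
within-module joins, so upper quantiles of the height distribution sit
essentially at the top of the dendrogram and either split tight blocks or
merge everything, whereas a fixed fraction of the span reliably falls in
the gap between "modules have assembled" and "modules join each other".
Clusters smaller than `minModuleSize` (default 30 genes) are pooled into
the reserved `"unassigned"` label. Module labels are deterministic —
ordered by size, named from a fixed color palette — so repeated runs are
byte-identical.

Average linkage is monotone in exact arithmetic; tied dissimilarities
(exactly-zero noise) can produce floating-point height inversions, which
are clamped with a running maximum before cutting.

Modules whose eigengenes are closer than `mergeCutHeight` in correlation
dissimilarity ($1 - \mathrm{cor}$, default cutline 0.2, i.e. eigengene
correlation ≥ 0.8) are merged iteratively, recomputing eigengenes each
pass, until no pair is below the cutline; the merged module keeps the
largest constituent's name. The emulated analyses state both a 0.2
dissimilarity cutline and a 0.75 correlation rule; the stricter 0.2 is
the default and the parameter is exposed. Raising the cutline can only reduce
the module count (verified as a property test).

## Eigengenes and module–trait statistics

A module eigengene is the first right-singular direction of the module's
gene-standardized block, rescaled to unit sample variance and oriented so
its correlation with the module's mean standardized profile is
non-negative; `varianceExplained` is the first squared singular value
over the total. A one-gene module's eigengene is that gene's standardized
profile. By the Eckart–Young property no unit-norm gene combination
explains more variance (spot-checked against 1,000 random directions).

Module–trait association is the Pearson correlation between eigengene and
numerically encoded trait — age in years; sex F = 0 / M = 1; two-level
groups 0/1; categorical traits with more levels as one-vs-rest
indicators, since a single correlation against an arbitrary integer
coding of a 3-level label is not well-defined. Two-sided p-values use
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df, which the test suite
cross-checks against a $10^5$-replicate permutation oracle; $|r| = 1$
underflows to the smallest representable double rather than 0. Gene
significance (GS) is the absolute gene–trait correlation and module
membership (MM) the gene–eigengene correlation, with the same transform.

## Preprocessing

`filterExpressed()` keeps genes exceeding a linear-scale threshold
(default FPKM-like value 1) in at least `minFraction` of samples. The
emulated wording "FPKM > 1 of all sequenced transcript" is read as *in
all samples* (`minFraction = 1`), the stricter of the two readings, and
the fraction is exposed. `log2Transform()` uses pseudocount 1, which
preserves zeros. `quantileNormalize()` delegates to
`limma::normalizeQuantiles` (ties receive the mean reference value;
idempotent). `detectOutlierSamples()` clusters samples by average linkage
on standardized-expression Euclidean distance and flags everything
outside the largest cluster at a cut of mean + 2.5 SD of the merge
heights; the rule is exposed because on strongly age-structured cohorts
it can flag an entire age group, which is why the network stage does not
remove outliers implicitly.

## Differential expression

`degTest()` offers Welch's unequal-variance t and a moderated t in the
empirical-Bayes tradition, re-implemented: pooled per-gene variances
$s_g^2$ on $d$ df are shrunk to
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$, with $(d_0, s_0^2)$
estimated by method of moments from $\log s_g^2$ (digamma/trigamma
moments of the scaled-F model; trigamma inverted by Newton iteration).
The moderated statistic has $d_0 + d$ df; as $d_0 \to \infty$ it becomes
a z-statistic at $s_0$ (tested as a limit identity), and the whole path
is cross-checked against `limma::eBayes` as an independent oracle. Genes
constant and equal in both groups get $p = 1$; constant but different,
the smallest representable p. DEG calls need both
$|\mathrm{logFC}| \ge$ `degLfcThreshold` (default 0.5; the emulated
analyses also use 1 for a small RNA-seq cohort, so it is per-run
configurable) and BH-adjusted $p <$ `degFdr` (default 0.05), with BH
computed over the tested (filtered) universe.

## Hub detection

Maximal cliques are enumerated with Bron–Kerbosch pivoting (igraph) and

$$\mathrm{MCC}(v) = \sum_{C \in S(v)} (|C| - 1)!$$

summed per node. Scores are integer-valued; they are exact in double
precision for clique sizes up to 18 ($17! < 2^{53}$), far beyond every
regime exercised here, and a warning flags anything larger. Isolated
nodes count their singleton maximal clique, $(1-1)! = 1$, configurable to
0. Ranking is MCC descending, degree descending, gene ID ascending —
fully deterministic. Enumeration is guarded by a 2,000-node ceiling
because worst-case clique counts are exponential. Top-k defaults to 5
hubs (the emulated analyses report both top-5 and top-6; k is a
parameter).

## Over-representation

`hypergeomUpperTail(k, K, n, N)` is the exact upper-tail probability of
drawing at least $k$ set members in a query of $n$ from a universe of $N$
containing $K$, computed through `phyper` (log-gamma based) and verified
against exhaustive exact-rational arithmetic for all $N \le 60$.
`runOra()` corrects with BH *within a collection* — GO-like and KEGG-like
collections are corrected separately, mirroring their separate cutoffs
(defaults 0.05 and 0.01) — and flags sets only when the overlap count
strictly exceeds `enrichMinCount` (default 6, the strict reading of
"count > 6"). The universe is the caller's: the convention here is all
genes surviving preprocessing in the analyzed cohort. TF-target and
miRNA-target collections reuse the same engine with user-supplied GMTs;
no databases are bundled.

## Age trajectories and cohort contrasts

The claim that the transcriptome changes abruptly in particular life
periods is a changepoint claim, so `fitTrajectory()` fits continuous
piecewise-linear least squares with 0, 1 or 2 breakpoints grid-searched
over the observed age range (1-year grid, breakpoints strictly interior,
each segment holding ≥ 2 observations, two breakpoints ≥ `minGap` = 10
years apart so a single kink cannot be fit twice) and selects the count
by BIC, charging two parameters per breakpoint (slope change + location).
Perfect fits are handled by flooring RSS at $n \times 10^{-20}$, which
reduces BIC comparison among exact fits to parameter counting. A cubic
smoothing spline is returned for plotting only; inference rests on the
piecewise-linear model. A quadratic-trend alternative is noted in the
emulated analyses' discussion but deliberately out of scope.

PC1 scores come from the SVD of the gene-standardized matrix with the
sign fixed so the age correlation (or, absent ages, the correlation with
mean expression) is non-negative, making cohort contrasts deterministic;
the variance fraction equals the eigengene's `varianceExplained` when
applied to a single module. Cohort contrasts use the Wilcoxon–Mann–Whitney
test: exact enumeration when both samples have ≤ 8 observations without
ties, otherwise the normal approximation with tie and continuity
corrections. `deltaDeltaCt()` implements $2^{-\Delta\Delta C_T}$ relative
quantification. `sharedSignature()` intersects two cohorts' age-related
module genes, intersects their DEGs within those modules, and scores the
overlap by the hypergeometric tail in the harmonized universe
(case-sensitive exact gene-ID matching; no symbol aliasing).

## The synthetic cohort generator

`simulateCohort()` draws ages uniformly over 21–93 years (the adult span
of the emulated design) with balanced sex labels, builds each planted
module as a factor model — eigengene = standardized age trend +
$N(0, \sigma_e)$ sample noise, gene = loading × eigengene +
$N(0, \sigma_g)$, loadings uniform in (0.5, 0.95) — and fills the
background with i.i.d. $N(0,1)$ genes. Defaults $\sigma_e = 0.3$,
$\sigma_g = 0.5$ give within-module gene correlations around 0.6–0.7,
strong but not degenerate co-expression. The factor model is chosen
because the pipeline's own module summary is a first principal component,
making the planted truth and the estimand the same kind of object. An
age-free module uses an independent standardized Gaussian eigengene, so
it is age-independent by construction. `toFpkmLike()` exponentiates to a
linear scale to exercise the expressed-gene filter. Generators are pure
functions of (parameters, seed) and restore the caller's RNG state.

Two design facts matter for recovery experiments. First, *distinct linear
slopes are not distinct signals*: standardization maps every linear age
effect onto the same trend, so a recovery cohort can contain at most one
linear module; the standard 10-module recovery design used in the tests
is therefore 8 age-free modules, one linear module (slope 0.05/year), and
one rise-and-fall module with its slope change at age 57 — the midpoint
of the age span, where its trend is nearly orthogonal to the linear one
for any age draw. Second, *a one-clique hub is not identifiable*: every
member of a single planted clique scores the same $(c-1)!$, so
`simulatePPI()` plants two cliques per hub by default (disjoint mate
pools within a module, intersecting only in the hub), which is also what
maximal-clique-centrality hubness means — membership in several cliques.
The hub then dominates its clique-mates by a full $(c-1)!$ margin.

`simulateTwoCohorts()` shares a module's gene membership verbatim across
cohorts (independent noise) and plants cohort-specific modules whose
genes are plain background noise in the other cohort, emulating a design
where part of the aging signature is ancestry-shared (the 95-gene shared
module used throughout the tests) and part is ancestry-specific.

**What the simulations do not emulate:** mixed cell-type composition and
its deconvolution structure, count-distribution artifacts (the generator
is Gaussian on a log-like scale), batch effects, correlated background
genes, microarray probe effects (one row per gene is assumed), and any
real PPI topology beyond planted cliques plus Erdős–Rényi background.
Passing recovery tests therefore shows the pipeline is correct and
well-calibrated under its own model, not that real PBMC data will be as
clean.

## Problem sizes and runtime envelope

The standard experiment sizes used in the test-suite and acceptance runs
are: 10 modules × 50 genes + 500 background genes × 60 samples for module
recovery (five seeds, plus a zero-noise run); 200 age-free modules for
module–trait calibration; 5,000 genes × 10 vs 10 samples for null
error-rate checks and 2,000 genes × 30 vs 30 with 300 planted logFC-1.5
genes for power; 300-node PPI graphs over 20 seeds for hub recovery;
n = 100 trajectories for breakpoint localization; and five two-cohort
runs (95 shared + 150 + 150 cohort-specific + 300 background genes, 60
samples per cohort) end-to-end. These sizes keep every gene set large
enough for stable rank statistics while the full suite runs in about a
minute; the TOM path is dense matrix algebra and comfortable to a few
thousand genes, which is the intended desk scale (no blockwise
approximation is provided).

## Known limitations

* Static-cut module detection, not dynamic-hybrid tree cutting; the cut
  fraction is exposed but results on real data will differ from
  WGCNA-with-dynamic-cut in the fine structure.
* Unsigned networks conflate positively and negatively age-correlated
  modules that are mutually anti-correlated; use `networkSign = "signed"`
  when direction matters.
* No covariate adjustment in the DE model (the emulated analyses fit
  none) and no count-specific weighting; inputs are expected on a
  log-like scale.
* MCC scores lose integer exactness beyond clique size 18 (warned).
* The hypergeometric overlap test for shared signatures treats gene sets
  as exchangeable draws from the universe, ignoring co-expression-induced
  dependence; its p-values are calibrated for ranking, not as literal
  error rates.
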