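---
title: "Methods: co-occurrence networks and N2O driver attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks and N2O driver attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`n2onet` implements an analysis chain used in soil microbial ecology to
relate community structure to potential denitrification-derived nitrous
oxide (N2O) emission: genus-level count tables from two kingdoms
(bacteria, fungi) are filtered and normalized, turned into signed
co-occurrence networks, summarised by topology, modularity, keystone
scores, robustness and cohesion, and finally connected to per-sample N2O
rates through regressions, non-parametric community tests and a
random-forest driver ranking. This vignette documents the statistical
model behind each stage, the defaults, and the numerical conventions.

# Preprocessing

## Low-abundance filter

`filter_low_abundance()` keeps a genus when its mean relative abundance
across samples is at least `min_rel_abund` (default `1e-4`) **and** it is
present (count > 0) in at least `min_prevalence` samples (default 2).
The prevalence floor of 2 is the weakest condition under which a
correlation across samples is even formally defined for the genus; the
relative-abundance floor removes genera whose counts are dominated by
sequencing noise at typical library sizes (1e-4 of a 2e4-read library is
two reads).

## TMM normalization

`tmm_factors()` computes trimmed-mean-of-M-values scaling factors. For a
library *k* against reference *r* (the library whose 75th-percentile
count fraction is closest to the mean of those fractions), genes with
finite log-ratios M and average log-abundances A are doubly trimmed
(30% of each M tail, 5% of each A tail) and the factor is the
precision-weighted mean of the surviving M values. Factors are rescaled
so their geometric mean is 1, making them pure relative-composition
corrections. Two invariants are guaranteed and tested: libraries with
identical compositions (counts proportional across columns) get factors
of exactly 1, and the geometric mean of any factor vector is 1 to 1e-9.
Correlation and topology stages consume `counts / effective_libsize`
(effective library size = library size x factor); diversity and cohesion
weights use plain proportions, which is deliberate: cohesion is an
abundance-weighted average and must stay on the simplex.

## Row z-scores

`zscore_rows()` standardizes each genus across samples to mean 0,
standard deviation 1 (denominator n-1). Zero-variance rows are set to 0,
flagged in an attribute, and a warning is raised: a constant genus has no
association information, and 0 is the unique value that leaves module
mean abundances unbiased.

# Network inference

`spearman_matrix()` uses mid-rank Spearman correlation. Two-sided
p-values come from the t approximation
t = rho * sqrt((n-2)/(1-rho^2)) with n-2 degrees of freedom; |rho| = 1
is assigned p = 0. Constant rows are flagged and given rho = 0, p = 1
against everything. The approximation's worst-case absolute deviation
from exact permutation enumeration is below 0.09 for n in 5..7 (0.16 at
n = 4); the test suite asserts this bound by full enumeration. At the
default edge thresholds and realistic n the approximation error is far
inside the decision margin.

`threshold_network()` calls an edge between genera i and j iff
|rho_ij| > `rho_min` (default 0.7) and p_ij < `p_max` (default 0.05);
the edge carries the correlation sign. These conventional thresholds
select strong, individually supported associations rather than
FDR-controlled discovery; Benjamini-Hochberg correction over the upper
triangle is available via `fdr = TRUE`. All filtered genera remain as
(possibly isolated) vertices so that per-sample and per-treatment
subnetworks — induced subgraphs on the genera observed in a sample or
treatment — are nested by construction.

# Topology, modules, keystones

`topology_summary()` reports edge counts by sign, the number of
non-isolated vertices V, average degree 2E/V, mean local clustering over
vertices with degree >= 2 (vertices with degree < 2 have no defined
triangle fraction and are excluded rather than zero-filled), Freeman
betweenness centralization sum(Bmax - Bi) / ((V-1)^2 (V-2) / 2) on the
non-isolated subgraph with topological (unweighted) shortest paths, and
the positive:negative edge ratio (Inf when no negative edges, NA when
edgeless). Every field is verified against a brute-force oracle
(triangle enumeration; BFS path counting) on random graphs.

`detect_modules()` runs seeded Louvain modularity maximization on the
unsigned, unweighted skeleton — correlation magnitudes already passed a
hard threshold, so edge weights are treated as evidence of association,
not of strength. Modules are relabeled in decreasing size order for
stable reporting. `within_module_degree_z()` computes
Zi = (kappa_i - mean(kappa)) / sd_pop(kappa) per module, using the
population standard deviation (the module is the whole population, not a
sample); modules with identical within-module degrees get Zi = 0 for all
members. The keystone cutoff is Zi >= 2.5, the customary hub threshold
in module-role taxonomies.

# Stability

`robustness_curve()` removes floor(f * V) uniformly chosen vertices and
reports the proportion of remaining vertices that are non-isolated,
averaged over `reps` (default 100) Monte-Carlo draws per fraction.
`compare_robustness()` applies Welch's t test to the replicate values of
two curves at a common fraction (default 0.5); two exactly constant
equal samples are reported as degenerate with p = 1.

`cohesion()` follows the connectedness-times-abundance construction:
each genus's positive (negative) connectedness is the mean of its
positive (negative) correlations with other genera, and a sample's
positive (negative) cohesion is the relative-abundance-weighted sum of
connectedness values. Positive cohesion is therefore >= 0 and negative
cohesion <= 0 on every input — a tested invariant. An optional
taxa-shuffle null model (`null_iters > 0`) subtracts the mean null
connectedness, clamped so the sign contract survives correction.

# Ecological statistics

`alpha_diversity()` returns Shannon H, Gini-Simpson 1 - sum(p^2),
Pielou H / ln S, Heip (e^H - 1)/(S - 1), Good's coverage
1 - singletons/reads, and (given a tree) Faith's PD including the path
to the root. `levins_breadth()` computes B = 1 / sum(q^2) over a genus's
distribution across samples within a treatment, so B ranges from 1
(specialist) to the number of samples (uniform generalist).

`anosim_test()` ranks all pairwise dissimilarities (mid-ranks) and
computes R = (mean between-group rank - mean within-group rank) / (M/2),
M = n(n-1)/2, with an add-one permutation p-value
(count + 1)/(n_perm + 1) — never exactly 0, and uniformly distributed
under the null up to discreteness, which the acceptance suite verifies
by calibration. `anova_lsd()` performs the one-way omnibus F test and,
for the post-hoc letters, pairwise t tests using the pooled ANOVA mean
square error (Fisher's LSD); letters are assigned to maximal cliques of
the "not significantly different" graph, ordered by group mean.

`n2o_rate()` converts headspace concentrations to total dissolved + gas
amounts with the Bunsen coefficient, total = conc * (v_gas + beta *
v_liquid) / v_liquid, and takes the OLS slope over incubation time.

# Driver attribution

`composite_index()` reduces a block of covariates to the first principal
component of their z-scores, sign-oriented to correlate non-negatively
with the row mean so that "more of the block" scores positive.
`rf_importance()` is a regression random forest (bootstrap resampling,
`mtry = max(1, floor(p/3))`, node size 5, CART variance-reduction
splits) implemented in C++ against R's own uniform RNG, so results are
exactly reproducible from a seed. Importance is the total node
sum-of-squares decrease attributable to each predictor, averaged over
trees ("increase in node purity"); model fit is out-of-bag R^2 =
1 - MSE_oob / var(y), which can be negative when predictors carry no
signal — by design, since OOB error is an honest estimate.
`permutation_significance()` refits the forest on `n_perm` response
permutations and reports add-one p-values per predictor and for the
model R^2. Its type-I error is calibration-tested.

# The synthetic generator

`generate_community()` draws latent module factors f_m with unit
variance around treatment-specific means, gives each genus in module m
the log-abundance mu_i + sqrt(latent_corr) * f_m + noise, and converts
log-abundances to counts through a softmax and a multinomial draw of
`library_size` reads — so the data are compositional by construction,
like real amplicon counts. N2O rates are a linear function of the module
factors plus Gaussian noise; background (module-0) genera are
independent. The generator emulates: compositionality, planted
correlation blocks, treatment-shifted module activity, and a
module-driven emission response. It does not emulate: taxonomic
structure, zero-inflation beyond multinomial sampling, phylogenetic
signal in abundances (trees are random), or spatial/temporal
autocorrelation.

Two presets are provided. `preset_paper_mimic()` is a small 3-treatment
x 3-replicate design (60 genera per kingdom) used for end-to-end runs;
its shift and effect magnitudes were calibrated analytically so that
treatment N2O means and network density land in realistic ranges for
paddy-to-vegetable conversion studies. `preset_power()` is the
high-replication variant (3 x 10 samples, latent_corr 0.9, module
effects -0.5/+0.5) used for recovery assertions — with 9 samples the
planted structure is not reliably recoverable, and the package does not
pretend otherwise. In the power preset the module-1 and module-2
treatment-shift vectors are chosen orthogonal (and mean-zero) across
treatments, so the treatment design itself induces no cross-module
correlation; without this, anti-parallel shifts create spurious
between-module edges that can fuse modules under Louvain.

Recovery is scored by the adjusted Rand index between detected and
planted partitions over the non-isolated vertices: isolated genera are
never assigned a module by network clustering, so including them would
score the edge-calling threshold, not the clustering.

# Determinism

Every stochastic stage takes an explicit seed. `run_all()` derives
per-stage, per-kingdom seeds from the single `run_config()` seed through
an affine map into [0, 2^31), and `report.json` is written without
timestamps, so two runs with the same configuration produce
byte-identical reports — a tested guarantee.

# Error handling

All user-facing failures are classed conditions under
`n2onet_config_error`, `n2onet_input_error`, `n2onet_consistency_error`
(which names the offending samples or taxa), `n2onet_parameter_error`
and friends, so pipelines can branch on failure type rather than match
messages.
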