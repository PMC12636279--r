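---
title: "Group-level structural covariance networks: methods and design choices"
author: "scovnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level structural covariance networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scovnet)
```

## The problem

A structural covariance network (SCN) is a group-level graph whose nodes are
brain regions and whose edges are the across-subject correlations of regional
gray-matter volumes.  Unlike tractography or functional connectivity, an SCN
is a property of a *cohort*, not of a single subject: with one volume table
per group you obtain one network per group.  This package implements that
analysis for region-of-interest (ROI) volume tables — the motivating
application is thalamic subdivisions in tremor cohorts with and without REM
sleep behavior disorder, but every stage is atlas-agnostic — together with
the graph-theoretic summaries and the permutation machinery needed to compare
groups.

The pipeline is:

1. **Normalization.** Each subject's ROI volumes are divided by that
   subject's total intracranial volume (TIV), giving dimensionless fractions
   in (0, 1).  This removes head-size scaling before any correlation is
   computed.
2. **Network construction.** Within one group, the edge between ROIs $i$ and
   $j$ is the Pearson correlation $r_{ij}$ of their volume fractions across
   subjects, or the partial Pearson correlation given covariates such as
   estimated intracranial volume (ICV).  Negative correlations are set to
   zero, the diagonal is zero, so the adjacency is symmetric with weights in
   $[0, 1]$.
3. **Graph metrics.** Per node: strength, normalized betweenness centrality,
   and the Onnela weighted clustering coefficient.  Globally: mean clustering
   $C$, characteristic path length $L$, and the small-world index
   $\sigma = \gamma / \lambda$ with $\gamma = C / C_{rand}$ and
   $\lambda = L / L_{rand}$ computed against an ensemble of degree-preserving
   rewired surrogates.
4. **Inference.** Per node and metric, a permutation test of the between-
   group difference with Benjamini–Hochberg false-discovery-rate (FDR)
   correction across nodes.

## Model details and conventions

Several choices are left open by common verbal descriptions of SCN analysis;
the package fixes them as follows and records each in output metadata.

**Edge definition.** Both plain Pearson on TIV fractions and partial Pearson
with covariates are supported.  Partial correlation is computed as the
Pearson correlation of residuals after least-squares projection of each ROI
vector onto an intercept plus the covariates, the standard definition.  The
pipeline default (`method = "auto"`) uses partial correlation with ICV when
an ICV covariate is present and plain Pearson otherwise.  Negative-edge
truncation is applied *after* the (partial) correlation, as a property of
the final adjacency.  A zero-variance ROI or covariate is an error, never a
silent `NaN`.

**Weight-to-distance map.** Path-based metrics need distances; a larger
covariance is read as a stronger connection, hence a shorter path, via
$d_{ij} = 1 / w_{ij}$ (the usual connectomics convention).  A zero weight is
"no edge".

**Betweenness.** Brandes accumulation over weighted shortest paths, counting
all shortest paths with multiplicity, normalized by $(n-1)(n-2)/2$ so values
lie in $[0, 1]$.  Unreachable pairs contribute nothing; an isolated node
scores 0.

**Weighted clustering.** The Onnela geometric-mean form
$$c_u = \frac{1}{\deg(u)\,(\deg(u) - 1)} \sum_{v \ne w}
\left(\hat w_{uv}\, \hat w_{uw}\, \hat w_{vw}\right)^{1/3},$$
with $\hat w = w / \max(w)$ normalized by the graph's **global** maximum
edge weight, $\deg(u)$ the count of strictly positive incident weights, and
the sum over *ordered* neighbor pairs (each triangle twice, which exactly
cancels the ordered-pair denominator; the test suite verifies equivalence
with the unordered form).  Nodes with fewer than two neighbors score 0, and
an edgeless graph returns all zeros rather than dividing by an undefined
maximum.

**Path length and disconnection.** $L$ averages shortest-path distances over
*reachable* unordered pairs only.  Truncation can disconnect a network; the
result then carries a disconnection flag rather than an infinite $L$, and
the pipeline logs a warning.

**Small-world normalization.** $C_{rand}$ and $L_{rand}$ are ensemble means
over degree-preserving rewired surrogates of the observed network (default
ensemble size 10,000 at study scale; simulations in this package's tests use
100–1,000 to keep runtimes reasonable, a choice the results are insensitive
to at the reported tolerances).  A complete graph admits no valid swap, so
its ensemble is itself and $\gamma = \lambda = \sigma = 1$ exactly — a
useful fixed-point check.

**Null model.** Surrogates are generated by double-edge swaps on the
positive-weight edge set: a swap of $(a,b), (c,d)$ to $(a,d), (c,b)$ is
accepted only when it creates no self-loop and no duplicate edge, and each
edge carries its weight through the swap.  This preserves the binary degree
sequence *and* the edge-weight multiset exactly (hence the total strength),
while per-node strength is free to vary — the most conservative weighted
extension of binary degree-preserving rewiring.  The default of 10 attempted
swaps per edge is a common mixing heuristic.  An alternative that rewires
the binary topology and reassigns weights at random would destroy the
weight–topology coupling; it was deliberately not made the default.

**Permutation inference.** The observed statistic is the per-node difference
$m_A - m_B$ (the A-minus-B convention is written into every output, since
published tables are often ambiguous about sign).  Two null models are
available:

* `rewire` — each permutation draws one rewired surrogate of each group
  network and records their metric difference.  This is the standard SCN
  procedure and the pipeline default.  Note what it tests: whether the
  observed difference is extreme *relative to networks with the same degrees
  and weights but scrambled topology*.  Because each surrogate preserves its
  own group's weight multiset, a global offset between groups is inherited
  by the null and therefore not, by itself, evidence.
* `subject_permutation` — group labels are shuffled across the pooled
  subject table and both networks are rebuilt from scratch each permutation.
  This is exchangeable under "no group difference" and is the only mode with
  a guaranteed type-I calibration property; it requires the volume tables,
  not just the networks.

Raw p-values use the add-one rule $p = (1 + b)/(1 + B)$, which cannot be
zero at finite permutations.  The default sidedness compares
$|\Delta_{null}| \ge |\Delta_{obs}|$; a literal one-sided "greater" rule is
available (`sidedness = "one_sided_greater"`) but a signed one-sided rule
would declare any large *negative* observed difference significant, so it is
not the default.  FDR correction is the Benjamini–Hochberg step-up across
nodes, implemented directly (and verified against both a brute-force
step-up search and `p.adjust`).

**Regional statistics.** ANCOVA per ROI is the nested-model F-test of the
group factor in `outcome ~ group + covariate`, with adjusted group means at
the covariate mean and Bonferroni correction over the ROI family (the family
size is a parameter).  The covariate-adjusted Spearman correlation is
computed as partial Pearson on ranks with a $t$ approximation on $n - 3$
degrees of freedom — "Spearman with a covariate" has no single canonical
definition, and rank-then-partial is the simplest one that inherits
monotone invariance (verified in the tests).

## The synthetic cohort generator

Subject-level volumes for the motivating study design are not publicly
deposited, so the package ships a generator that emulates the *structure*
such data would have, with known ground truth:

* TIV fractions are drawn from a multivariate normal with a target
  correlation matrix; draws with non-positive entries are rejected and
  resampled (an error is raised if acceptance falls below 1%).  A normal on
  fractions keeps the Pearson target directly interpretable; volumes are
  emitted *unnormalized* (fraction × simulated TIV) so the pipeline's own
  normalization is exercised.
* The default correlation target couples the 14 left/right homologous
  nucleus pairs at $r = 0.65$ over an $r = 0.25$ background — mimicking the
  elevated bilateral coupling characteristic of thalamic volumetric data —
  and the shipped three-group scenario (`defaultScenario()`) uses group
  sizes 45 / 41 / 10 with the geniculate-body edges raised by $+0.25$ only
  in the smallest group, the design the inference stage is meant to detect.
* Group-specific edge perturbations are added to the base correlation and
  the result is repaired to the nearest positive-semidefinite correlation
  matrix by eigenvalue clipping followed by diagonal rescaling.
* Mean fractions (defaults between $1.5\times10^{-4}$ and $8\times10^{-4}$
  of TIV, larger for pulvinar/mediodorsal-like nuclei, small for geniculate
  bodies), a per-ROI coefficient of variation of 0.15, and TIV
  $\sim \mathcal N(1.45\times10^6, (1.3\times10^5)^2)$ mm³ truncated to
  positive values are realistic magnitudes for thalamic nuclei in adults.

What the generator does **not** emulate: segmentation noise, scanner and
site effects, atlas misregistration, non-Gaussian tails, or age/sex
structure.  Passing tests on synthetic cohorts therefore demonstrate the
*statistical machinery* — calibration, determinism, oracle agreement — not
robustness to real-world imaging artifacts.

## What the simulations can and cannot detect

The test suite verifies type-I calibration of the subject-permutation mode
(two groups of 45 and 41 drawn from one recipe; the mean per-node raw
rejection rate at $\alpha = 0.05$ is required to sit in $[0.02, 0.09]$) and
probes effect recovery with a planted $+0.4$ correlation increase on the
three edges among three designated nuclei at $n = 40$ per group.

It is worth being explicit about the power arithmetic of that second
scenario, because it is unforgiving.  At $n = 40$ the sampling standard
deviation of a correlation near $r = 0.25$ is roughly $(1 - r^2)/\sqrt{n}
\approx 0.15$, so a $+0.4$ edge effect is only about a 2.5-SD event *per
edge*; nodal strength then dilutes the two perturbed edges of each
designated node with the sampling noise of its 25 unperturbed edges, and
FDR correction across 28 nodes raises the effective threshold further.  The
permutation null also inherits extra spread from the planted effect itself
(label shuffling mixes the perturbed edges into both pseudo-groups).  The
high-recovery regime for this design therefore requires larger samples,
larger perturbations, or more perturbed edges per node; at these settings
per-node FDR flag rates are low, and the corresponding acceptance check
documents the shortfall rather than hiding it.  The same arithmetic explains
why small clinical cohorts report few FDR-surviving nodal differences unless
the underlying effect is very large.

The `rewire` null has a complementary limitation the reader should know:
dense truncated covariance networks (positive background correlation makes
most of the $\binom{28}{2}$ edges positive) admit few valid double-edge
swaps, so surrogates stay close to the observed network and the null
distribution concentrates near the observed difference.  On such networks
the rewiring test is conservative by construction.  This is a property of
the procedure itself, faithfully implemented; the subject-permutation mode
exists precisely because it tests the group-difference hypothesis with
guaranteed calibration.

## Reproducibility

Every stochastic stage takes an integer seed.  Ensembles and permutation
streams derive per-draw sub-seeds from the root seed by a fixed counter
scheme, so results are byte-reproducible and independent of evaluation
order, and the pipeline writes a manifest (configuration, seeds, package
version) sufficient to replay a run.  The determinism contract is tested
end-to-end: two pipeline runs with one seed must produce identical tables.

Problem sizes used by the test suite — 100 random graphs of up to 10 nodes
against brute-force oracles, 200-member null ensembles, 20-seed small-world
sweeps, 200 calibration replicates at 500 permutations, 50 recovery
replicates at 1,000 permutations, and end-to-end runs at 500 permutations —
were chosen so the full suite completes in minutes on a single core while
keeping Monte-Carlo error well inside the asserted bounds.

## Known limitations

* Group-level networks mean no per-subject network, hence no subject-level
  covariate adjustment beyond the partial-correlation option and no
  longitudinal modelling.
* No sparsity thresholding or density matching across groups is offered:
  the weighted truncated matrix is analyzed directly, so group differences
  in overall correlation level propagate into strength differences (by
  design — see the null-model discussion above).
* The betweenness distance map ($1/w$) is a convention; metrics that depend
  on it should be compared across groups, not interpreted in absolute
  units.
* `weightedClustering` normalizes by the global maximum weight; comparing
  clustering values *between* networks implicitly compares them relative to
  each network's own strongest edge.
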