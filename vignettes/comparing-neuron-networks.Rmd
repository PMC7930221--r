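---
title: "Comparing neuron feature tables with Gaussian Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing neuron feature tables with Gaussian Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogbn)
```

## The model and its assumptions

`neurogbn` analyzes tables of continuous per-cell variables — typically
electrophysiological features (input resistance, action-potential threshold,
peak, amplitude, rise/fall times, ...) and dendritic morphometrics — for two
groups of neurons, such as human and mouse layer 2/3 pyramidal cells. The
core object is a Gaussian Bayesian network B = (G, θ): a DAG G over the
variables in which each node carries a linear-Gaussian conditional density

N(x_i ; β_i0 + β_iᵀ pa(x_i), σ_i²),

so the joint factorizes over parent sets and is itself multivariate normal.
The model therefore assumes (approximately) jointly Gaussian, linear
dependencies; heavy tails, nonlinearities and interactions are outside the
model class and will be absorbed into residual variances. Arcs encode
conditional-independence structure, not causal claims: Markov-equivalent
DAGs fit data equally well, which is why results are reported at the level
of the CPDAG (edges directed only where every equivalent DAG agrees) and of
quantities invariant within the equivalence class (BIC, the implied joint,
partial correlations).

All learning operates on z-standardized columns (mean 0, SD 1, denominator
N − 1). Standardization is required by the precision-matrix identity below,
does not change which structures the BIC prefers (rescaling a column shifts
every candidate family score for that node by the same constant), and
leaves Pearson correlations untouched.

## Parameter fitting and scoring

Each node is fitted by ordinary least squares on its parents. Residual
variances use the maximum-likelihood denominator N, not the regression
default N − p − 1: this keeps the BIC an exact penalized log-likelihood.
The score, in natural logs and with higher better, is

BIC(G) = Σ_i [ log L_i − (k_i / 2) log N ],  k_i = |Pa(i)| + 2,

counting intercept, parent coefficients and variance per node. Other k_i
conventions shift all structures by a constant per node and do not change
the argmax; the convention is fixed so that scores are reproducible across
implementations. Fits are computed from one cached Gram matrix of
(1, X), making a family score O(p³) regardless of N — the search and the
bootstrap depend on this. A rank-deficient parent design raises an error
naming the node rather than silently regularizing.

## Structure search

`tabu_search()` starts from the empty graph (the common default; the
original analysis does not state its initial graph) and repeatedly applies
the best legal single-arc addition, deletion or reversal, excluding
blacklisted pairs in both directions. Score-degrading moves are accepted;
the move that would undo a recently applied operator is tabu for
`tabu_list_size` iterations (default 30), with the standard aspiration
exception when a tabu move would beat the best score seen. The search stops
after `max_nonimproving` (default 30) consecutive accepted moves without a
new best score and returns the best structure seen. Ties between
equal-scoring moves break lexicographically by operator, child, parent, so
the search is fully deterministic; the `seed` argument exists only for API
symmetry with the bootstrap. There is no cap on parent-set size — at the
sample sizes involved the BIC penalty and the singular-fit guard bound it
in practice. `exhaustive_search()` (n ≤ 5) is the enumeration oracle used
by the tests, not a user-facing learner.

## Bootstrap arc confidence and blacklisting

With N of order 20–40 and 10–30 variables, many structures score nearly
alike. `bootstrap_networks()` learns structures on B resamples (size N,
with replacement); `arc_confidence()` estimates p(X→Y) as the replicate
frequency of each directed arc; and `build_blacklist()` marks the unordered
pair {X, Y} spurious iff p(X→Y) + p(X←Y) ≤ t. Directions are pooled because
at these sample sizes orientations are rarely stable even when adjacency
is. The threshold is inclusive (≤ t), following the formula in the source
analysis over its looser prose ("below 0.7"); the boundary case is pinned
by tests. Defaults are B = 2000 and t = 0.7 — the study-scale settings; the
package's own experiments (`confidence_separation_experiment()`) show why a
t above 0.5 is needed: spurious pairs' confidences are inflated at small N
and overlap the nonspurious range.

Standardization is computed once on the original sample, not per resample:
location and scale do not affect which arcs are found, and a shared scale
keeps replicates comparable. A resample that leaves a column constant
(possible at N ≈ 21 with ties) is rejected and redrawn from the same
replicate RNG stream, with a message; letting the BIC handle a
zero-variance node was rejected as numerically fragile. Replicate seeds
derive deterministically from the master seed, so doubling B extends rather
than reshuffles the replicate set only in the sense of determinism — the
estimates converge at the usual Monte-Carlo rate either way.

## Precision matrices and partial correlations

For standardized variables the precision matrix follows directly from the
fitted parameters, Ω = (I−B) S⁻¹ (I−B)ᵀ with B the matrix of parent
coefficients and S the diagonal of residual variances — no inversion of an
empirical covariance, so Ω exists even when N ≤ n. Partial correlations are
ρ_XY|Z = −Ω_XY / √(Ω_XX Ω_YY); they are exactly zero precisely when X and Y
are non-adjacent in the moral graph of G, so the network's sparsity
translates into exact conditional independencies. Marginal correlation
networks, by contrast, are built from the *empirical* correlation matrix
(threshold |ρ| > τ, strict), because the blacklist-regularized network
shrinks many marginal correlations to zero by construction.

## Comparing groups

`compare_networks()` reports two Hellinger distances, one per data set. The
structure learned on group A is re-fitted on group B's data and compared,
via the implied joints, with the network fitted on B (and vice versa).
Because any OLS-fitted network on a given data set implies exactly that
data set's mean vector, both distributions in each comparison share their
means by construction — a guard asserts this to 1e-8 — and the closed form

H = √(1 − det(Σ₁)^¼ det(Σ₂)^¼ / det((Σ₁+Σ₂)/2)^½)

depends on covariances only. It is evaluated through Cholesky
log-determinants, which keeps it stable for the ill-conditioned covariances
that sparse structures on standardized data can produce; H is clamped to
[0, 1] against rounding at the boundary. H = 0 means identical covariance
structure; values near 1 mean the two structures explain each other's data
very differently. The report also lists CPDAG common arcs — an edge counts
as common only if both adjacency and orientation class (same compelled
direction, or undirected in both) agree — and per-variable Markov-blanket
equality.

`welch_t_table()` uses Welch's unequal-variance t-test (two-sided): group
SDs in this setting differ by up to a factor of two, and the source
analysis does not state a variant. `subgroup_correlations()` splits cells
at a cutpoint on a depth variable (value ≤ cutpoint is the "below"
subgroup) and contrasts pooled with within-subgroup Pearson correlations;
Simpson-style sign reversals between the pooled and subgroup estimates are
exactly the pattern it exists to expose. Note the biological reading of
"below": relative cortical depth runs from 0 at the pia to 1 at the white
matter, so cells *spatially* below a depth plane have *larger* rel-depth
values; the function is purely numeric and leaves that mapping to the
caller.

## Morphometry

`compute_features()` derives nine features per arbor class (basal, SWC type
3; apical, type 4): mean path distance from the arbor's insertion point to
its bifurcations; mean branch length; mean tortuosity (geodesic over chord
length per branch, ≥ 1); mean remote bifurcation angle (angle at the fork
between vectors to the daughter branches' end nodes; multifurcations
average over daughter pairs); mean branch diameter (2 × radius,
compartment-length-weighted within a branch — the weighting is not
specified upstream and is fixed here); height/width/depth (coordinate
extents along Y/X/Z, reconstruction-frame and deliberately not
rotation-invariant); and total dendritic length. Branches are maximal paths
between topological events (insertion, bifurcation, terminal) and
partition the arbor's compartments; soma compartments are excluded, the
insertion point being the first dendritic node. "Averaged over all
bifurcation points" for mean branch length is read as averaged over
branches, consistent with the feature's name; the literal
bifurcation-weighted variant is available as
`mean_branch_length(weighting = "bifurcations")`. Undefined features
(absent arbor, no bifurcation) propagate as `NA`, and
`swc_feature_table()` drops incomplete cells with a warning rather than
imputing. Multiple arbors of one class are pooled before averaging, giving
one cell-level value per feature.

## Synthetic data: what it emulates and what it does not

The generator exists to provide ground truth, not biology. `random_dag()`
draws a uniform topological order and includes forward arcs independently;
`random_parameters()` sets intercepts to 0 (everything downstream is
location-invariant), draws coefficients uniformly outside a dead zone
(−0.1, 0.1) so no true arc is vacuous, and variances uniformly from a
positive interval; `sample_gbn()` performs ancestral sampling.
`make_confidence_scenario()` fixes the strong-signal profile (dead zone
0.5, variances 0.5–1.5, arc density 0.25) used for arc-confidence
experiments at the study's shapes (n = 11 with N = 42 or 21). Defaults were
chosen once as a realistic stand-in for standardized biological features
with moderate dependence; they are documented, seeded, and not tuned to
test outcomes. The source analysis reports its own confidence statistics
from an undescribed synthetic design, so those exact numbers (nonspurious
never below 0.48, spurious max 0.86) are not reproduction targets — only
the qualitative separation is, and the tests assert exactly that. A green
synthetic test therefore establishes that the machinery is correct under
the stated model, not that the model fits any particular empirical sample:
the generator makes no attempt to mimic empirical means, SDs, skews, or
measurement error of real cell tables.

## Numerical choices and degenerate inputs

- Natural logarithms throughout; BIC comparisons use an absolute tie
  tolerance of 1e-10.
- Family scores come from Gram-matrix algebra; residual sums of squares are
  clamped at 0 against cancellation.
- CPDAGs are computed by v-structure preservation plus orientation-
  propagation rules to a fixpoint; brute-force equivalence-class
  enumeration is kept in the test suite as the oracle (exhaustive on all
  DAGs with up to 4 nodes).
- Hellinger requires symmetric positive-definite covariances (Cholesky
  failure propagates as an error) and equal means to 1e-8.
- Constant columns: an error in standardization and correlation networks
  (named column); a redraw in bootstrap resampling.
- `run_study()` derives one RNG substream per group × subset from the
  master seed by hashing the stage label, so adding a subset never perturbs
  the seeds — and hence the outputs — of existing stages. Two runs with the
  same configuration and seed produce byte-identical artifacts.

## Known limitations

- Linear-Gaussian conditionals only; no discrete or conditional-Gaussian
  nodes, and no inference engine beyond the implied joint.
- Extents are reconstruction-frame; no pia-alignment rotation is applied.
- No structural-significance testing (e.g. permutation tests on graphs):
  Hellinger distances are reported descriptively, as in the source
  analysis.
- The bootstrap is embarrassingly parallel but runs serially here;
  B = 2000 on 30 variables is minutes, not seconds, of compute.
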