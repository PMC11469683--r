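---
title: "Connectivity states, transition dynamics and control energy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity states, transition dynamics and control energy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the methods it implements: the
models, the tunable parameters and their defaults, what the synthetic cohort
does and does not emulate, and the numerical choices made where the design
was genuinely open. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## From regional signals to edge time series

The pipeline starts from per-subject regional BOLD time series (frames x
regions). Each region is z-scored with its temporal mean and **population**
SD (denominator `n`). The edge time series of a region pair is the framewise
product of the two z-scored signals,

$$e_{ij}(t) = z_i(t)\, z_j(t),$$

so each frame carries a full co-fluctuation network and the temporal mean of
an edge series equals the Pearson correlation of the pair *exactly* — the
identity holds only under the population-SD convention, which is why that
convention is pinned (`zscore_regional()`) and asserted to 1e-10 in the
tests. Only the upper triangle (`i < j`, row-major) is stored; frames are
reconstructed on demand with `frame_matrix()`.

## Connectivity states: city-block k-means and the elbow

Edge frames are pooled across subjects and clustered with k-means under the
city-block (L1) metric, the variant in which the centroid update is the
componentwise **median** of the assigned frames (the L1-optimal centroid —
Lloyd iterations with means would not minimise L1 inertia). Details that the
clustering literature leaves open are pinned as follows:

* **Seeding.** Each of the 5 replicates uses k-means++-style seeding
  (distance-proportional sampling under L1); the replicate with minimal
  total inertia is kept, so adding replicates can never raise the reported
  inertia. Replicate `r` is seeded with `seed + r`, making replicate sets
  nest.
* **Empty clusters** are reseeded from the frame farthest from its assigned
  centroid, with a logged message.
* **Convergence.** Iterations stop when assignments stabilise, when the
  relative inertia improvement drops below `rel_tol = 1e-6`, or at
  `max_iter = 100`. The tolerance cuts a long tail in which single frames
  shuffle between equivalent clusters at merged model orders (k below the
  true number of states) with negligible inertia change; setting
  `rel_tol = 0` recovers exact assignment-stability convergence.

The number of states is chosen over k = 2..7 by the elbow criterion,
implemented as the k whose point on the inertia curve lies at maximal
perpendicular distance from the straight line joining the curve's endpoints,
ties broken toward smaller k. A non-monotone curve (possible with finite
replicates) is first smoothed by decreasing isotonic regression, with a
warning; a near-linear decline returns the smallest interior k with a
"no elbow" warning. The rule is deterministic and testable; nothing else
about the elbow is assumed.

State centroids are described with graph metrics: global mean connectivity
is the mean of the *signed* centroid; global efficiency (mean inverse
shortest-path length, edge length `1/|w|`), Louvain modularity (best of 10
seeded restarts, ties to the lowest seed) and eigenvector centrality
(principal eigenvector of `|W|`, unit Euclidean norm, averaged within each
resting-state network) use the elementwise absolute value, because path
lengths and centralities are undefined for signed weights. The alternative
(positive part instead of `|w|`) changes only `describe_state()` inputs and
is a one-line edit; the absolute-value convention is the package's pinned
choice. States are named after the network with maximal mean centrality.

## State dynamics

A subject's state sequence is reduced to: total transitions (count of
`s(t) != s(t+1)`); fractional occupancy (fraction of frames per state,
summing to 1); and the directional transition-probability matrix, where row
`i` counts ordered consecutive pairs leaving state `i` — *including*
persistence `i -> i` — divided by all pairs starting in `i`. Rows of states
with no outgoing pairs (never visited before the final frame) are missing,
never zero-filled: downstream statistics see the reduced `n`, not an
imputed value.

## Minimum control energy on the structural connectome

The brain is modelled as a continuous-time linear system on the subject's
structural connectome, `x'(t) = A x(t) + u(t)`, with every region a control
node (`B = I`). The connectome is stabilised as

$$A = \frac{W}{\lambda_{max}(W) + c} - I, \qquad c = 1,$$

which places the spectrum of `A` in `[-2, 0)`. The minimum-energy input
steering `x_0` to `x_f` over horizon `T` has cost
`v' W_T^{-1} v` with `v = x_f - e^{AT} x_0` and the controllability Gramian
`W_T = \int_0^T e^{At} B B' e^{A't} dt`. The Gramian is computed by the Van
Loan augmented-matrix-exponential construction (exact to matrix-exponential
precision — no quadrature step size), and verified in the tests against a
Simpson-quadrature oracle, a scalar closed form, and an independent
Euler-discretised optimal-control oracle (0.5% relative). Per-region
energies `\int u_i^{*2} dt` are evaluated in spectral closed form (A is
symmetric for symmetric connectomes) and sum to the total exactly. A Gramian
with condition number above 1e12 is inverted by a relative-tolerance
eigenvalue pseudo-inverse with a logged warning; at the defaults the Gramian
is well conditioned.

Each subject's z-scored activity frames (the same normalisation as the edge
construction — the pipeline has exactly one normalised activity
representation) are treated as system states, the energy of every
consecutive-frame transition is computed with the per-subject propagator and
Gramian factorisation reused, and energies are averaged by the state
transition type of each frame pair into a k x k matrix (unobserved
transition types are missing). Each cell is then z-scored against the
healthy-control distribution of that cell (sample SD over controls; cells
with fewer than 2 control values or zero control SD are flagged unusable).
Total / persistence / transition control energy are the means over all,
diagonal and off-diagonal non-missing cells. Within-subject averaging
precedes across-subject z-scoring.

**Control horizon.** `T` is exposed everywhere and defaults to `T = 3`. The
horizon governs how strongly the natural decay `e^{AT}` differentiates weak
from intact connectomes: at very short horizons the propagator is close to
the identity for every subject and a global loss of structural coupling is
barely expressed in the energy, while the effect compounds as `T` grows and
saturates for large `T`. The default is the interior of the grid
`{0.5, 1, 3, 5}` examined by `horizon_energy_stability()`, chosen where the
structural mechanism the synthetic cohort plants is clearly expressed;
mirroring how the horizon is selected data-drivenly in empirical work with
this model class. The stabilisation constant `c = 1` is likewise
configurable; only the ratio `c / \lambda_{max}` matters for the spectrum.

## Cognitive classification

Raw domain scores (7 domains) are adjusted with least-squares models of
score on age, sex and binary education fitted **in healthy controls only**;
all subjects are residualised with the control-fitted coefficients, and
residuals are z-scored by the control residual mean and SD. Two pinned
details: the residual SD uses the regression's residual degrees of freedom
(`n - p`, not `n - 1`; the naive denominator understates the control spread
and inflates every |z|), and adjustment is per *domain* (one score per
domain; mapping tests to domains is metadata). A covariate constant within
controls is dropped with a warning. Classification is CI when at least 2 of
7 domains fall strictly below -2, else MCI when at least 2 fall strictly
below -1.5, else CP; both inequalities are strict, so a z of exactly -2.0
counts toward MCI but not CI (measure-zero impact on continuous scores).

## Group statistics

With purely cross-sectional, between-subject data no random effects are
identifiable, so the parametric route is fixed-effects least squares
`dv ~ group + age + sex + education`, with a partial F-test for the group
factor and the CI-vs-CP contrast (CP as reference) with its 95% CI.
Variables failing a Lilliefors-style KS normality check take Quade's
nonparametric ANCOVA: ranks (midranks for ties) of the outcome and of each
covariate across the full sample, least-squares regression of ranked
outcome on ranked covariates, and a one-way ANOVA F-test on the residuals
across groups — with zero covariates this collapses to a one-way ANOVA on
ranks. Quade's procedure has published variants; the residual-ANOVA form is
pinned and its type-I error is calibration-tested (0.05 ± 0.02 under 1,000
null simulations at n = 60) rather than assumed. Bonferroni families are
the measures tested within one analysis block (e.g. the per-state occupancy
tests, or the three energy summaries). Partial correlations residualise
both variables on the covariates and use `df = n - 2 - q`. All analyses are
complete-case; missing dynamics or energy values reduce `n`, never impute.

## The synthetic cohort: what it emulates, and what it does not

No data are deposited with the empirical study the pipeline is designed
around, so validation uses a generator with full ground truth. The default
configuration (`default_cohort_config()`) encodes the study conditions:

* **Scan geometry.** 200 analysed frames (a 202-volume acquisition minus 2
  discarded volumes), 100 regions partitioned into 8 resting-state networks
  and 4 structural modules.
* **States.** 4 hidden states realised as orthonormal activation templates
  that are piecewise constant over the structural modules
  (`generate_module_templates()`). Module alignment is deliberate: real
  coactivation patterns express structural communities, and it places
  activity in the connectome's slow eigenmodes — the regime in which
  white-matter integrity measurably shapes control energy. Fully random
  orthonormal templates (`generate_state_templates()`) are available and
  are the right choice when no structure-function coupling is wanted.
* **Frames.** Frame `t` is `amplitude(t) x template[s(t)] + N(0, 0.02^2)`
  noise, with `|amplitude| ~ Uniform(0.8, 1.2)` and a random sign per
  frame. The random sign makes regional signals sign-ambiguous while edge
  patterns (pairwise products) stay sign-stable per state, which is what
  frame clustering relies on. The amplitude range is kept narrow
  deliberately: with a wide range (e.g. 0.5-1.5) the low-amplitude frames
  of *all* states collapse toward the origin of edge space and k-means
  devotes a spurious central cluster to them, distorting model-order
  selection; at 0.8-1.2 amplitude still varies but state geometry dominates.
* **Dynamics.** Hidden Markov chains started from their stationary
  distribution (no burn-in sensitivity). HC/CP persistence 0.75 (about 50
  expected transitions in 200 frames) vs CI persistence 0.85 (about 30) —
  the directionality and scale of the empirical groups, with a larger
  planted gap so recovery is well powered at 20 subjects per group.
* **Connectomes.** Stochastic block structure over the 4 modules with
  log-normal weights (within-module median 0.04, between 0.002, log-SD
  0.3), symmetric, hollow, fully connected. The scale puts
  `\lambda_{max}` near 1, where the stabilised dynamics remain sensitive to
  a global integrity factor; much heavier raw weights would be normalised
  away (`\gamma` enters only through `\gamma\lambda_{max} + c`). CI
  connectomes are scaled by integrity 0.7, CP/HC by 1.0.
* **Cognition.** Raw scores are linear in age/sex/education plus a group
  deficit plus noise, so the control-referenced adjustment has real
  structure to remove. CI deficits are -3.5 residual SDs on three domains;
  the default cohort plants no MCI subjects (the -1.5 SD band is
  intrinsically noisy at n = 20).

Passing tests on this cohort demonstrate that the pipeline recovers planted
model order, state sequences, Markov structure, group directions and
classification labels under controlled conditions. They do **not**
demonstrate robustness to what the generator omits: hemodynamic convolution,
scanner noise and motion artifacts, head-size or atlas effects, non-Markov
state dynamics, heterogeneous (lesion-localised rather than global)
white-matter damage, or empirically realistic between-subject topology
variation.

## Problem sizes and determinism

The default cohort is 60 subjects x 200 frames x 100 regions (12,000 pooled
frames x 4,950 edges); the k = 2..7 sweep with 5 replicates runs in a few
minutes on one CPU, and the calibration studies use 1,000 null simulations
at n = 60. Every stochastic step (templates, chains, connectomes, scores,
seeding) flows from a single integer seed; identical configuration and seed
reproduce the cohort and the fits bit for bit.
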