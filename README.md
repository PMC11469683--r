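# brainstates

Dynamic functional brain-network analysis in R: from regional BOLD time
series and structural connectomes to recurrent connectivity states, state
transition statistics, and network-control-theory transition energies, with
covariate-adjusted group statistics and healthy-control-referenced cognitive
classification. The package is aimed at researchers studying how cognitive
impairment (for example in multiple sclerosis) relates to altered brain
dynamics, and at methodologists who want a tested, fully synthetic-validated
implementation of this analysis chain.

## The analysis

**Edge time series.** Regional signals are z-scored (population SD) and each
region pair's co-fluctuation is the framewise product
e_ij(t) = z_i(t) z_j(t), so the temporal mean of every edge series equals
the pair's Pearson correlation exactly — a temporal unwrapping of static
functional connectivity.

**Connectivity states.** Edge frames pooled across subjects are clustered
with city-block k-means (componentwise-median centroids, 5 replicates); the
number of states is selected by the elbow of the inertia curve over
k = 2..7. Each subject's frame-wise state sequence yields total transitions,
fractional occupancy, and the directional transition-probability matrix
T_ij (persistence on the diagonal; rows of unvisited states are missing).
Centroids are described by global mean connectivity, global efficiency,
modularity and per-network eigenvector centrality, and named after the
network with maximal centrality.

**Control energy.** On the subject's structural connectome W the brain is
modelled as x'(t) = A x(t) + u(t) with A = W/(λ_max(W)+c) − I and every
region a control node. The minimum control energy of the transition between
consecutive activity frames is E_min = v' W_T⁻¹ v with
v = x_f − e^{AT} x_0 and controllability Gramian
W_T = ∫₀ᵀ e^{At} B B' e^{A't} dt (computed by the augmented matrix
exponential, not quadrature). Framewise energies are averaged by transition
type into a k × k matrix per subject, z-scored per cell against healthy
controls, and summarised as total, persistence (diagonal) and transition
(off-diagonal) control energy.

**Cognition and statistics.** Seven cognitive domain scores are adjusted
for age, sex and education with models fitted in healthy controls,
z-scored against the control residuals, and classified: CI (≥ 2/7 domains
Z < −2), MCI (≥ 2/7 domains Z < −1.5), else CP. Group comparisons use
fixed-effects ANCOVA or Quade's rank ANCOVA (routed by a Lilliefors KS
check), CI-vs-CP contrasts with CP as reference, Bonferroni families per
analysis block, and covariate-adjusted partial correlations.

**Synthetic cohort.** `generate_cohort()` plants ground truth for all of
the above: hidden Markov state sequences over module-aligned activation
templates, group-specific transition rates and structural integrity, and
planted cognitive deficits — so every stage of the pipeline is validated by
recovery of known truth. See the methods vignette
(`vignettes/connectivity-state-dynamics.Rmd`) for the model and every
tunable default.

## Worked example

The `analysis/` scripts run the whole study on the default synthetic cohort
(60 subjects: 20 HC / 20 CP / 20 CI, 200 frames, 100 regions, 4 planted
states) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # cohort + ground truth
Rscript analysis/02_states.R      # edges, k-means sweep, elbow, descriptors
Rscript analysis/03_dynamics.R    # transitions, occupancy, T_ij
Rscript analysis/04_energy.R      # control energies, HC-z, summaries
Rscript analysis/05_cognition.R   # HC-referenced z-scores, CP/MCI/CI
Rscript analysis/06_group_stats.R # ANCOVA + partial correlations
```

Output of an actual run (seed 42):

```
planted mean total transitions: HC 49.2, CP 48.9, CI 29.9
elbow selects k = 4 connectivity states
state names (network of maximal eigenvector centrality): S1=DMN, S2=SMN, S3=VIS, S4=VAN
mean transition CE (HC-z): HC 0.01, CP 0.03, CI 0.84
planted patient labels recovered: 90%
           measure method           F p_bonferroni          beta
 total_transitions linear 76.65931281 1.680339e-16 -20.805437960
          total_ce  quade 23.76086650 9.379215e-08  19.887491215
    persistence_ce linear 23.03070653 1.756118e-07   0.789508670
     transition_ce  quade 18.01735958 2.589230e-06  19.699305758
partial correlation (transitions vs transition CE | age, sex, education): r = -0.63, p = 1.39e-07, n = 60
```

Reading these numbers: the elbow recovers the 4 planted states; cognitively
impaired subjects make about 21 fewer state transitions than preserved
subjects (the planted lower off-diagonal Markov mass) and need more control
energy to transition between states (their connectomes were generated with
integrity 0.7 vs 1.0) — their mean transition energy sits 0.84
control-referenced SDs above the healthy controls; and fewer transitions go
hand in hand with higher transition energy (r = −0.63 after covariate
adjustment).

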