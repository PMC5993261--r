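---
title: "Methods: sliding-window connectivity states and network metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window connectivity states and network metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstates)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the numerical choices made
where several were defensible, and what the synthetic-data validation
does and does not demonstrate.

## The analysis model

The unit of input is a per-subject, per-run matrix of node time courses
(volumes x nodes, sampling interval `trSeconds`), with per-node
metadata: a subnetwork label and a 3-D centroid in millimetres. Nodes
are typically ICA components; the package consumes time courses only
and performs no spatial processing.

**Preparation** is a fixed sequence: discard the first `nDiscard`
volumes (default 4 — scanner signal stabilization), remove each node's
mean and linear trend by least squares, and low-pass filter. The filter
is a zero-phase forward-backward Butterworth of order 5 (default cutoff
0.15 Hz): zero-phase matters because a causal filter would shift state
boundaries in time, and order 5 run twice gives about 35 dB of
attenuation at 1.5x the cutoff while leaving the passband flat. The
`prepState` flag on the object enforces the order and prevents double
filtering; detrending is idempotent. Per-node QC reports the dynamic
range of the Welch power spectrum (segment length 64 volumes, 50%
overlap, Hann window) and the ratio of integrated power below a split
frequency (default 0.10 Hz) to power above it; real analyses retain
components dominated by low-frequency fluctuations. No numeric
inclusion threshold is hard-coded: the split frequency and any cutoff
are configuration.

**Windowed connectivity.** Windows are `windowLength` volumes long
(default 15, i.e. 30 s at TR = 2 s) and advance by `step` volumes
(default 1). The 15/1 reading — window *length* 15 with a sliding step
of one volume — is deliberate: overlapping windows require the step to
be smaller than the length, and ~30 s windows are the established
working point for task-based dynamic connectivity. Both numbers are
configurable. Per window the estimator is either the (optionally
taper-weighted) Pearson correlation of the windowed rows, or the
partial-correlation matrix derived from an L1-penalized precision
estimate. Clustering features are the vectorized upper triangles of
whichever estimator is configured; correlation is the default because
it is parameter-free, and the precision route is provided for parity
with pipelines that regularize short-window covariances.

**Sparse precision.** The estimator minimizes
`tr(S Theta) - log det(Theta) + rho * ||offdiag(Theta)||_1` over
positive-definite matrices by proximal gradient descent (ISTA) with
backtracking. This choice (over coordinate-descent graphical lasso) is
deliberate: backtracking proximal gradient decreases the primal
objective at every iteration by construction, which turns the
"objective non-increasing" contract into a testable invariant, and the
soft-threshold step produces exact zeros. At `rho = 0` the solver is
bypassed and the inverse returned (well-conditioned input required). A
15-volume window over more than 15 nodes has a singular sample
covariance, and with an off-diagonal-only penalty the objective is then
unbounded below; windowed covariances are therefore ridge-stabilized by
flooring the minimum eigenvalue at 1e-3 of the mean diagonal before
solving. Convergence is declared when the relative objective change
falls below `tol` (default 1e-10); exceeding `maxIter` is an error, not
a silent truncation.

**State clustering** is k-means with squared Euclidean distance, run in
two phases as is standard for dFC state analysis: (1) *exemplar*
windows — local maxima of the across-edge variance profile of each run,
boundary windows counting as maxima when they exceed their single
neighbour — are pooled and clustered with `nReplicates` seeded random
starts, keeping the best inertia; (2) a single Lloyd run over *all*
pooled windows starts from the phase-1 centroids. Windows from both
groups and both runs are pooled so states are shared objects, and
labels are split back per subject-run afterwards. Empty clusters are
re-seeded at the point farthest from its centroid — a deterministic,
documented rule. Everything is reproducible from one integer seed.

The number of states `k` is scanned over 2..8 when requested: for each
`k` the cohort-mean frequency of every state is computed, a `k` is
flagged when more than half of its states fall below the top of the
low-occupancy band (default 0.04, i.e. states occupying only a few
percent of windows), and the recommended `k` is the largest unflagged
value. The flagging rule is an explicit heuristic standing in for a
judgment the field usually makes by eye.

**State metrics.** Frequency is the fraction of a run's windows per
state; a transition is any adjacent pair of unequal window labels; the
dwell time of a state is the mean length of its maximal
constant-label runs, in windows (and in seconds when the step duration
is supplied), undefined (`NA`) for unvisited states. These definitions
make the identity `visits = transitions + 1` exact, which the tests
exploit.

**Graph metrics.** Static graphs come from the full-run correlation
matrix: each edge's p-value from the correlation-to-t transform with
`n - 2` degrees of freedom, Benjamini-Hochberg step-up over the
`n(n-1)/2` unique edges at level `alpha` (default 0.05), survivors
keeping their signed weight. Binary metrics are computed on the
surviving mask: the local clustering coefficient
`C_i = 2 e_i / (k_i (k_i - 1))` (defined as 0 when the degree is
below 2, where the ratio is undefined), and the average shortest path
length as the mean unweighted hop distance over ordered *reachable*
pairs, with the reachable fraction reported alongside — on a complete
graph the path length is exactly 1 and global efficiency, its
reciprocal, is 1. Weighted metrics use absolute weights: network
strength sums `|w_ij|`, and the cost of an edge is the Euclidean
distance between its nodes' centroids times `|w_ij|`, so node costs sum
to exactly twice the network cost. Negative correlations therefore
contribute their magnitude to strength and cost and count as edges when
FDR-significant. Hubs are nodes whose metric exceeds the mean by more
than `sdMultiplier` (default 1.5) sample standard deviations; because
the defining phrase "highly connected" is used for degree-, strength-
and cost-based rankings in different places, the hub finder accepts any
node-metric vector and the report records which was used (pipeline
default: cost). State-level graphs are built by unvectorizing a
centroid and applying a recorded edge-retention rule (default: top 10%
of |weight|), since centroids are dense averages with no significance
structure of their own.

**Group statistics.** Test-retest reliability correlates each metric
between runs within group (Pearson, two-sided t-based p). Two-sample
comparisons use Welch's unequal-variance t-test — the conservative
default when no test is otherwise specified. The dominant-state test
assigns each subject the state with maximal run-averaged frequency
(ties broken to the lowest state id, deterministically) and applies
Pearson's chi-square without continuity correction, reporting expected
counts and warning on cells below 5. Correlation tables report raw
Pearson r/p with an optional BH column; no adjustment is ever applied
silently, and no sign conventions are imposed on behavioral scores.

## The synthetic cohort generator

The generator emulates the study design the pipeline is meant for: two
groups (default 20 subjects each), two runs per subject, 240 volumes at
TR = 2 s, 20 nodes in four subnetwork blocks, and four latent
connectivity states. Each state is a block-structured SPD correlation
matrix: a distinct subset of subnetwork blocks is compound-symmetric at
`couplingStrength` (default 0.8, jittered per state by up to 10% so
states are generic), everything else uncorrelated. Latent states follow
a volume-level Markov chain; emissions are zero-mean Gaussians with the
active state's correlation matrix plus isotropic noise
(`noiseSd` = 0.5), so observed correlations are attenuated by
1/(1 + noiseSd^2) but the block geometry is preserved. State changes
occur at volume boundaries — the simplest model consistent with
window-level analysis.

Group models are "sticky" chains (uniform switching at self-transition
0.965 for the control-like group, 0.972 for the clinical-like group,
putting expected volume-level transition counts near 8.4 and 6.7 per
run), and a group can be denied access to designated rare states by
zeroing their columns, which reproduces the observed structure where a
few clinical subjects occupy states never visited by controls.

Subject heterogeneity is the part of the design that required the most
care. Perturbing each transition row independently produces cohorts
whose run-to-run state frequencies are only weakly reliable (r ~ 0.6):
nothing anchors a subject to a characteristic state, so run-level
sampling noise dominates. Real cohorts look different — between-subject
frequency SDs of 0.2-0.35 with many subjects effectively locked into a
dominant state across both runs. The generator therefore draws, per
subject, a Dirichlet *preference profile* over states (concentration
`subjectConcentration`, default 0.4 — small values give strongly locked
subjects) together with a log-normal switching-rate multiplier
(`rateSd`, default 1.0). Switch destinations are proportional to
preference, exit rates scale with (1 - preference) normalized so the
occupancy-weighted switch rate matches the group rate on average (with
per-row exit rates capped at twice the group rate so excursions are not
arbitrarily brief), and each run starts in the subject's preferred
state. The defaults were calibrated once, against the target dispersion
above (frequency SD ~ 0.3, transition SD ~ 5, means ~ 7-8 per run), and
then frozen. For experiments that manipulate *group-level* dynamics
(e.g. sticky vs mobile groups), the appropriate cohort is instead
group-typed: `subjectConcentration = 50`, `rateSd = 0.25`, so the group
contrast is not swamped by individual preference variance. Both regimes
are plain `cohortSpec()` settings, not code paths.

What passing the validation experiments shows: the pipeline recovers
planted block-structured states (window-label agreement, frequency and
transition-count recovery), reproduces a planted group difference in
switching rate across the whole k-scan, and yields reliable
frequencies when subjects are genuinely preference-stable. What it does
not show: robustness to hemodynamic convolution, temporal
autocorrelation within states (emissions are i.i.d. given the state — a
modeling choice, since within-state noise spectra are not
characterized), motion or physiological artifacts, imperfect
parcellations, or non-block covariance geometry. Results on real fMRI
derivatives depend on all of these.

## Numerical choices and degenerate inputs

* Constant nodes inside a window zero the affected correlations with a
  warning rather than aborting; constant nodes in QC yield `NA`.
* Taper default is rectangular; a Gaussian taper is available.
* k-means ties in nearest-centroid assignment break to the
  lowest-index centroid; `k` larger than the number of distinct
  windows is an error.
* The brute-force-verifiable contracts (clustering coefficient, path
  length, BH step-up, Welch/chi-square statistics) are tested against
  independent naive implementations, not against the routines that
  produce them.
* All randomness flows from explicit integer seeds; cohorts are pure
  functions of their `CohortSpec`, and the pipeline's output tables
  carry a config-hash provenance header and are write-once per run
  directory.

## Validation problem sizes

The experiment scale used by the validation suite: the recovery and
reliability experiments use the default cohort (2 x 20 subjects x 2
runs x 240 volumes x 20 nodes, 4 states, seed 1); the
diminished-dynamics experiment uses 20 replicate cohorts of 2 x 20
subjects x 1 run with k scanned over 2..8; graph-metric oracles cover
every graph on up to 6 nodes plus 100 random 20-node graphs; null
calibrations use 200-400 Monte-Carlo replicates. These sizes make the
full suite run in a few minutes on one CPU while keeping every
experiment's sampling error well inside its decision margin.

## Known limitations

* The occupancy-based `k` recommendation is a heuristic; on data with
  well-separated but balanced states it tends to recommend the top of
  the scanned range, because k-means splits balanced clusters into
  non-empty halves rather than leaving near-empty states.
* Window-level transition counts are resolution-limited: latent dwells
  much shorter than half a window are invisible, so estimated counts
  compress true volume-level counts (monotonically, which is why
  recovery is assessed by correlation rather than absolute agreement).
* The sparse-precision estimator is quadratic-to-cubic per window in
  the node count; for large parcellations with step-1 windows the
  correlation estimator is the practical default.
* No hidden-Markov or change-point inference is performed on the
  analysis side; HMMs exist only in the generator.
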