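---
title: "Static and dynamic functional connectivity with dynfc: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic functional connectivity with dynfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfc)
```

## The analysis in one paragraph

`dynfc` analyses resting-state fMRI that has already been reduced to
independent-component time courses (one signal per network node, here 43
components grouped into seven canonical networks: SCN, AUD, SMN, VIS, CCN,
DMN, CBN). After conditioning and motion QC, it computes (i) *static*
functional connectivity — full-series Pearson correlation between component
pairs, Fisher z-transformed; (ii) *dynamic* connectivity — the same
correlation inside a tapered window slid one TR at a time; (iii) recurring
*connectivity states* — k-means centroids over all subjects' windowed
matrices, with per-subject fraction rate, mean dwell time and transition
count; (iv) per-edge *temporal variance* across windows; (v) *graph
topology* — binary graphs at proportional sparsity thresholds 0.08–0.48,
small-world coefficients and efficiencies, summarized by the area under the
metric-versus-sparsity curve (AUC) and, per window, by the across-window
variance of that AUC; and (vi) covariate-adjusted *group statistics* with
Benjamini–Hochberg FDR control, Kruskal–Wallis tests with Dunn post-hocs,
and partial correlations between dynamic properties and cognition (MoCA).
A Markov-switching Gaussian generator produces synthetic cohorts with known
ground truth so that every stage can be validated without scan data.

## Time-course conditioning

Conditioning is fixed to **discard → detrend → despike → low-pass**:

* the first 10 volumes of a raw acquisition are discarded for signal
  stabilization (a 7.5-minute scan at TR = 2 s collects 225 volumes and
  retains 215). Synthetic cohorts are generated *post-discard* and are
  recognized as such by the preprocessing stage;
* detrending removes a per-component least-squares linear trend (constant
  components become zeros);
* despiking replaces samples whose robust z-score
  $|x - \mathrm{med}| / (1.4826\,\mathrm{MAD})$ exceeds 4 by linear
  interpolation between the nearest clean neighbours. When more than half
  the samples are identical the MAD degenerates to zero; the scale then
  falls back to $1.4826$ times the mean absolute deviation so an isolated
  spike on a flat background is still caught, while exactly constant
  components pass through. The threshold is configurable; the algorithm
  itself is a package choice, since only the *presence* of a despiking step
  is standard;
* low-pass filtering uses a 5th-order Butterworth at 0.15 Hz applied
  forward and backward (zero phase). No high-pass is applied — the
  conditioning names only a high-frequency cutoff. The component-selection
  helper `power_ratio()` integrates a Welch periodogram (Hann segments of
  `min(T, 64)` samples, 50% overlap) over 0–0.10 Hz versus 0.15–0.25 Hz;
  components dominated by slow fluctuations score above 4. The band edges
  are configurable; these defaults follow the component-selection
  literature for TR = 2 s acquisitions.

Motion QC excludes subjects with mean frame-wise displacement above
0.2 mm or any translation/rotation beyond 3 mm / 3°.

## Windowing and the window count

Windows are 22 TR long with a Gaussian taper (σ = 3 TR): a rectangle
convolved with a Gaussian kernel supported on ±3σ, truncated to the
central 22 samples and normalized to unit sum. As σ → 0 the taper tends to
the flat window, in which case windowed correlation equals plain Pearson
correlation on the slice — the oracle equivalence the tests exploit.

With T = 215 and L = 22 the natural sliding count is T − L + 1 = 194, but
the analysis this pipeline reproduces uses **193** windows. `windowed_fc()`
therefore defines onsets 1 … T − L (W = T − L), matching the established
count; the discrepancy of one window is a documented convention, has no
effect on any statistic beyond the window count itself, and is asserted in
the tests.

Degenerate windows (zero weighted variance for a component) yield zero
edges for that window and are counted rather than aborting a cohort run.

## Connectivity states

All subjects' windowed matrices are flattened to upper-triangle edge
vectors (a fixed row-major edge order shared by every module) and pooled;
k-means with squared-Euclidean distance, k-means++ seeding, Lloyd
iterations (cap 500) and 150 restarts clusters them. Restarts that end
with an empty cluster are re-seeded and counted. The number of states is
chosen by the mean silhouette over k = 2…8, computed with Euclidean
distances on the same vectors; for cost the silhouette uses an evenly
strided subsample of at most 20 000 windows by default (5 000 in the
package tests), which is deterministic. Ties go to the smaller k.

Per subject, `state_metrics()` reports the fraction of windows in each
state, the mean dwell time (mean maximal-run length, in windows; a
TR-seconds conversion is included), and the transition count. States a
subject never visits get an `NA` dwell time and are dropped listwise from
group tests — zero-filling would bias group means downward.

Because k-means labels are arbitrary, all recovery analyses first match
fitted states to reference states by maximal centroid correlation
(`match_states()`); every downstream metric is invariant to relabelling.

**Resolution limit.** Sliding-window dwell estimates are only meaningful
when true dwell times are at or above the window length and the states are
separated well enough that per-window label noise does not fragment long
runs: label errors at rate ε cap observed runs near 1/ε windows, and the
22-TR window absorbs shorter excursions entirely. The dwell-monotonicity
property is therefore tested with strongly separated states and true
dwells of 22–110 TRs; users should treat absolute dwell values near or
below the window length as unreliable.

## Graph topology

Connectivity matrices are binarized by *proportional thresholding*: only
positive edges are ranked (descending) and the top `round(s·C(C−1)/2)`
are kept, for s on the grid 0.08–0.48 in 0.01 steps (41 thresholds). Ties
are broken by the fixed lexicographic edge order, so graphs are identical
across platforms; if fewer positive edges exist than requested, all are
kept and the achieved sparsity recorded.

On each binary graph the package computes the clustering coefficient
(`2·triangles/deg(deg−1)`, degree < 2 contributing 0), characteristic path
length over *connected* pairs only (the excluded fraction is reported —
graphs at sparsity 0.08 are routinely disconnected), global efficiency
(mean inverse shortest-path length, unreachable pairs contributing 0) and
local efficiency (mean global efficiency of each node's neighbour
subgraph). Shortest paths and triangle counts are delegated to igraph;
the test suite verifies every metric against brute-force Floyd–Warshall
and triangle-enumeration oracles on small random graphs.

Gamma and lambda normalize clustering and path length by the means over
degree-preserving random references (double-edge-swap rewiring, 10 swaps
per edge; connectedness is not enforced); sigma = gamma/lambda. The
reference count is not standardized anywhere; the package defaults to 100
for static graphs and 20 per window for dynamic curves, both configurable
and recorded in provenance. If the references carry no triangles, gamma
(and hence sigma) is undefined and propagated as `NA`.

Each metric's curve over the grid is summarized by the trapezoid-rule AUC
(grid width 0.40, so a flat curve of value m integrates to 0.40·m). The
dynamic analysis repeats the sweep per window and reports the variance of
the per-window AUC; all windows share one reference seed stream so that
identical windows give exactly zero variance and results stay
deterministic.

## Group statistics

The group analysis is a direct covariate-adjusted univariate screen: for
each feature (edge, network-block value, or metric AUC) a linear model
with intercept, two group dummies (HC as reference) and the nuisance
covariates age, sex (0/1), education and mean FD is compared by exact
F-test against the covariates-only model, followed by Benjamini–Hochberg
FDR at q = 0.05. This deliberately replaces a multivariate screen with
backward selection; in the operative analysis that screen reduced to
group-only univariate tests, so the simplification changes nothing
downstream and is far easier to validate. Non-normal temporal properties
use Kruskal–Wallis with ties correction and Dunn pairwise z-tests,
Bonferroni-multiplied. Associations with cognition use partial
correlations on covariate-adjusted residuals with df = n − 2 − k; both raw
and BH-adjusted p-values are reported, since such correlations are
conventionally read at uncorrected thresholds but the adjusted values cost
nothing.

## The synthetic cohort generator

The generator is the package's ground-truth instrument, not a fixture: a
two-state (configurable) Markov-switching multivariate Gaussian.

* **States.** State I ("within-network dominant") has block correlations
  `within = 0.45` inside networks and `between = 0.12` across them. State
  II ("between-network dominant") keeps the within-block level and raises
  between-network blocks 60% of the way toward it (0.318 by default). A
  literal swap of the two strengths is *not* a valid correlation matrix —
  strong global between-network correlation with weak within-network
  correlation violates positive definiteness — and the chosen shape is
  also what such states look like in real data: networks stay internally
  coherent while their mutual coupling strengthens. Matrices are jittered
  (sd 0.02), symmetrized, repaired by clamping eigenvalues at 1e-4 and
  rescaling to unit diagonal; repairs that would move any entry by more
  than 0.1 abort with an error instead of silently distorting the design.
* **Dynamics.** Each subject's hidden state follows their group's Markov
  chain from its stationary distribution. Default chains give stationary
  occupancy of the within-network state of about 0.71 (HC), 0.67 (LTLE)
  and 0.44 (RTLE): the patient-like right-lateralized group spends less
  time in the within-network state and more in the between-network state,
  with longer dwell there.
* **Group connectivity effects** act multiplicatively on covariance blocks
  (not on time courses), so effect sizes read directly in correlation
  units: the RTLE-like group scales cortical–cortical blocks by 0.75 and
  subcortical–cortical (SCN–other) blocks by 1.8. The left-lateralized
  group deliberately carries no effects. Magnitudes are free parameters of
  the design (no effect sizes are published for these contrasts); the
  defaults were chosen once so the injected SCN–SMN shift is comfortably
  detectable at n = 30/group (per-edge Cohen's d near 1) without being a
  caricature, and are exposed on the cohort specification object.
* **Observation model.** At each TR the observation is N(0, Σ_state) plus
  independent N(0, 0.3²) noise, attenuating correlations by ~8%.
* **Metadata.** Age ~ N(30, 8) truncated to [18, 60], education
  ~ N(13, 2.5), sex Bernoulli(0.5), per-volume FD from a gamma with mean
  |N(0.08, 0.04)| + 0.01 (mean FD is recomputed from the trace, keeping the
  two consistent). MoCA-style sub-items (standard domain ranges summing to
  30) sit near ceiling except one configurable linked item — language by
  default — generated as `2.8 − 6·(occ₂ − 0.35)` plus N(0, 0.7), rounded
  and clipped to [0, 3], where occ₂ is the subject's realized occupancy of
  the between-network state. The negative slope encodes "more time in the
  between-network state, worse performance", giving the
  partial-correlation stage a recoverable, sign-known signal.
* **Determinism.** Per-subject simulation and metadata seeds are drawn
  from the master seed, so identical spec + seed reproduce a cohort
  byte-for-byte.

What the generator does **not** emulate: hemodynamics, spatial structure,
ICA mixing artifacts, physiological noise spectra, scanner drift beyond
what conditioning removes, or realistic MoCA item correlations. Passing
tests demonstrate that the pipeline recovers the statistical structure it
assumes — switching covariance states, block-level group effects, a
monotone cognition link — not that it would behave identically on any
particular clinical sample.

## Numerical choices and degenerate inputs

* Fisher transform clips r at ±(1 − 1e−7); diagonals are zeroed on the z
  scale and excluded from every edge statistic.
* Constant components produce zero edges with a warning (static) or
  zero-filled, counted windows (dynamic) rather than failures.
* Both-models-perfect fits in the group F-test return F = 0, p = 1 by
  convention.
* The silhouette subsample, threshold tie-breaks, per-stage seeds (drawn
  from the master seed via a recorded counter) and the shared per-window
  reference seed stream make every pipeline output reproducible; the
  provenance record stores the config hash, stage seeds and versions.
* All k-means restarts use k-means++ seeding (the initialization is not
  standardized anywhere; k-means++ is the field default) on top of
  `stats::kmeans` Lloyd iterations.

## Problem sizes used by the shipped tests and acceptance script

The package's own validation runs at sizes chosen to exercise every code
path at full fidelity where it matters (43 components, 215 TRs, 193
windows) while keeping cohort counts and k-means restarts modest: 20–26
subjects and 5 restarts for state-count selection, 200 null cohorts of 90
subjects for the FDR operating-characteristic check, 50 cohorts of 90 for
effect and sign recovery (1 restart, well-separated states converge in a
handful of Lloyd iterations), and 10 cohorts of 30 for occupancy recovery.
These are the package's chosen validation sizes; all of them are plain
function arguments, so heavier runs only require larger values.

## Known limitations

* Dwell times near or below the window length are structurally
  overestimated and mutually indistinguishable (see the resolution note
  above).
* Proportional thresholding with few positive edges (heavily negative
  matrices) caps achieved sparsity below the requested level; the package
  warns and records the achieved value.
* The univariate F-test screen assumes exchangeable residuals per feature;
  it does not model spatial correlation between edges (the FDR is
  controlled per family of edge tests, which the null-cohort suite
  verifies empirically).
* `char_path_length` on a graph with no connected pairs is `NA`, and
  small-world coefficients on triangle-free references are `NA`; AUC
  treats `NA` metric values as 0 with a warning, which callers can avoid
  by restricting the metric set or the grid.
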