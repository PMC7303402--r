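---
title: "Methods: condition-weighted connectome graph analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condition-weighted connectome graph analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connsweep)
```

# The analysis model

connsweep implements a group-comparison pipeline for task-fMRI functional
connectomes. The unit of analysis is a participant's session: a T × 160
matrix of ROI BOLD series on a six-network functional atlas, six
realignment parameters, nuisance (white-matter/CSF stand-in) channels and a
block design alternating a visual *motion* condition with a *static*
condition (defaults: TR 2.45 s, 260 volumes, 27.5 s blocks, 12 cycles; a
design whose nominal span exceeds the scanned interval is truncated to it,
never dropped, so the 12-cycle design clips at 637 s).

The chain of assumptions, stage by stage:

**Motion screening.** Framewise displacement follows the rigid-body RMS
convention: for consecutive realignment rows, the relative transform's
linear part A and translation t give
`FD = sqrt((R^2/5) tr(A'A) + t't)` with R = 80 mm — the mean squared
displacement of a uniform ball of that radius. The radius is a convention,
not estimated from data. Task coupling of motion is the Pearson correlation
between FD and the *raw* 0/1 motion boxcar (the convolved variant is
available as an option). Exclusion is a single pass: a 3 mm / 3° ceiling on
absolute realignment parameters, then within-group |z| > 3 on mean FD and on
the task–FD correlation; survivors are not re-screened. A caveat
documented as part of the contract: rotations must arrive in radians —
degrees are indistinguishable from data alone.

**Denoising** happens in a fixed order — confound regression, then
discrete-cosine high-pass (0.008 Hz), then linear detrend, then despiking —
because regression residuals are what the later nonlinear steps should see.
The confound set is 5 principal components of the nuisance channels
(mean-centered, variance-ordered, sign fixed by the largest loading), the 6
realignment parameters, the HRF-convolved task regressors of *both*
conditions (so task co-activation cannot masquerade as connectivity), and
optionally one indicator column per high-FD frame (default threshold 0.5 mm
when enabled), which forces those frames' residuals to zero. The detrend is
technically partially redundant with the DCT basis; both are applied, in
the listed order, because the despike scale should be estimated on fully
detrended data. Despiking is a soft clip
`x <- m + s tanh((x - m)/s)` with m the node median and s = 3 robust sd
(1.4826·MAD): values within one sd move by well under 6 %, while arbitrarily
large spikes saturate at 3 robust sd. Nothing low-passes the data; the
spectrum above the drift band is preserved.

**Condition-specific connectivity.** Each scan is weighted by the
HRF-convolved boxcar of the condition, negatives clipped to zero. Weighted
Pearson correlations use frequency-weight semantics (invariant to weight
rescaling, so no renormalization is needed). The correlation is capped at
1 − 1e-7 before the Fisher transform so that degenerate, near-duplicate
nodes cannot inject infinities; anticorrelations are then *zeroed*, not
absolute-valued — negative coupling is treated as absent, a modelling
choice the downstream metrics inherit. The exact weighting kernel of the
toolbox that popularized condition-weighted connectivity additionally
tapers condition boundaries; that taper is undocumented, so connsweep uses
the plain clipped convolved boxcar and records the divergence here.

**Cost sweep and graph measures.** Proportional thresholding keeps the
`round(cost · n(n−1)/2)` largest weights as binary edges; ties break by
(row, column) lexical order so results are platform-reproducible, and
zero weights are never promoted to edges even when the cost demands it
(a warning reports the shortfall — expected at high costs on rectified
matrices, which zero roughly half of all entries). The main grid is
0.04–0.30 in steps of 0.01 — 27 costs; a printed account of the same
procedure elsewhere mentions "35 thresholds", which its own range/step
contradicts, and the range wins here. Degree, clustering and eccentricity
are computed on each binary graph. Eccentricity uses the within-component
convention (the maximum *finite* hop distance; isolated nodes score 0 and
are flagged): propagating infinities would destroy the AUC summaries on
the occasional disconnected low-cost graph; a strict mode
(`on_disconnected = "error"`) is available. Node curves are integrated by
the trapezoid rule over [0.04, 0.30], giving 160 × 3 AUC values per
condition.

**Null models and the small-world regime.** Random nulls are
degree-preserving double-edge swaps, approximately 100 attempts per edge
(the rewiring parameter); lattice nulls accept a swap only when it strictly
reduces the total |i − j| edge span, driving edges toward the diagonal
under the same degree constraint. Both are built per cost from the
thresholded graph. Efficiency curves run on their own grid, 0.01–0.59 in
steps of 0.02 (30 costs; a nominal upper end of 0.60 is unreachable from
0.01 in steps of 0.02, so 0.59 is the last grid point). The small-world
regime is the longest contiguous run of costs where the real graph's
global efficiency lies strictly between lattice and random and its local
efficiency strictly between random and lattice. Screening uses the pooled
(participant-mean) static-condition matrix by default; per-participant
screening is a caller choice. Local efficiency follows the
neighbor-induced-subgraph definition (the convention of the brain
connectivity toolbox family); note that some graph libraries implement a
remove-the-vertex variant that differs numerically.

**Summaries and decomposition.** Network summaries are unweighted means of
member-node AUCs: 6 networks × 3 measures per condition, deltas defined as
motion − static (computed on network means; the mean is linear, so
node-then-mean and mean-then-delta agree). The decomposition reduces the
weighted matrix to one partition of a focal network's pairs — within-network
(square block), sensorimotor↔cerebellar (rectangular block), or focal-to-
rest (rectangular) — and thresholds each partition at its own density,
`round(cost · n_admissible_pairs)` retained entries. Density relative to
admissible pairs is the natural extension of proportional thresholding to
rectangular blocks, which the source procedure left unspecified. Because
each partition is thresholded separately, partition degrees only sum to the
full degree *before* thresholding, and the test suite asserts exactly that.

# The statistical battery

The split-plot layout is classical sums of squares, not REML: exact F
tests under normality, homoscedasticity and (for the unadjusted within
tests) sphericity, and directly simulable. For each analysis family
(static, motion, delta) and measure, the model is

```
value ~ (group + age_c) * network + Error(participant/network)
```

with age centered at the grand mean. The between stratum tests group and
age against subjects-within-group (error df n − 3); the within stratum
operates on orthonormal network contrasts and tests network,
group × network and age × network against the network × subject error
(error df (k − 1)(n − 3)). Type III sums of squares are used (groups are
generally unbalanced); the implementation reproduces the car/afex family
to numerical precision, which the test suite asserts. Including
age × network in the within stratum follows the error-df pattern of the
published analyses this package reimplements; a covariate-in-between-only
layout would leave (k − 1)(n − 2) within dfs instead.

Sphericity is assessed on the contrast-residual covariance:
Mauchly's `W = det(S) / (tr(S)/(k−1))^(k−1)` with the standard chi-square
approximation, and Greenhouse–Geisser
`epsilon = (sum lambda)^2 / ((k−1) sum lambda^2)`. Policy: GG-adjusted
p-values are reported when Mauchly's p < .05, raw otherwise (configurable
to always/never). Under a true null this conditional procedure is very
slightly conservative; the calibration study below measures it.

The omnibus test is a doubly-multivariate Pillai's trace: between-subject
effects on the subject-mean (DC, CC, ECC) vectors, within-subject effects
on the stacked network-contrast scores of all measures (15 response
dimensions for 6 networks × 3 measures). Linearly dependent measure
columns are dropped by rank before testing, so a degenerate duplicated DV
set collapses to the corresponding lower-dimensional analysis. Published
multivariate dfs in this literature (e.g. an interaction on 465 error dfs
with 35 participants) imply an observations-as-rows layout that ignores
the repeated-measures structure; connsweep reports dfs from its own layout
and does not attempt to reproduce those numbers.

Post hoc contrasts are the 2-group difference of covariate-adjusted cell
means within each network. The variance pools both strata,
`(MS_between + (k−1) MS_within)/k`, with Satterthwaite dfs, plus the
covariate-adjustment term. The family is the k within-level group
contrasts, adjusted by the studentized range with the number of means
chosen so that its implied pairwise family matches the contrast count
(k_means solving choose(k_means, 2) = k — the convention of the emmeans
family for non-pairwise Tukey adjustment; a family of one reduces exactly
to the unadjusted p). By pipeline policy, contrasts are refused unless the
upstream fit showed a significant group effect or group × network
interaction (`force = TRUE` overrides). The decomposition ANOVA reuses the
same machinery with the three connectivity types as the within factor and
no covariate; the published account announces it as "2 × 2" while listing
three connectivity types — connsweep implements 2 groups × 3 types and
leaves the label mismatch unresolved.

An optional report flag (not a gate) marks whether omnibus p-values
survive a Bonferroni criterion of .05/3 across the three analysis
families; the package reports raw p-values.

# The synthetic cohort generator

The generator exists so that every downstream stage can be validated
against known ground truth; it emulates the study conditions, and its
defaults are fixed, not tuning knobs.

Signal model: each network has a shared latent series; node i in network
ν is `sqrt(c_t) L_ν,t + sqrt(1 − c_t) ε_i,t`, with both parts
unit-variance AR(1) (ρ = 0.3, mimicking BOLD autocorrelation) and the
coupling c_t modulated around a base of 0.3 through the unit-peak
HRF-convolved condition regressors by per-(group, network, condition)
deltas. This latent-factor construction is positive semi-definite by
construction and makes the within-network correlation equal the coupling
(attenuated ~5 % by measurement noise, sd 0.1, and cosine drift, amplitude
0.3 at 0.002–0.006 Hz — inside the high-pass stopband). Couplings escaping
[0, 1) after modulation are an error, not silently repaired. The default
deltas encode the qualitative group structure the analysis is meant to
recover — patients couple the sensorimotor network more strongly under
motion (+0.15) and the cerebellum less (−0.10), with a static-condition
bias in the opposite direction and a default-mode elevation at rest;
magnitudes are moderate correlation-scale values chosen once, since no
effect sizes are published for this design. Group sizes default to 18
controls and 17 patients; ages are uniform on [20, 60] with no age effect
by default. One 260-volume run is simulated per participant — whether the
original three-run sessions were ever concatenated is unstated, and the
analyzed data were single completed sessions.

Head motion is a six-channel random walk (step sd 0.02 mm / 2e-4 rad)
whose step variance is scaled by `1 + 3·coupling·regressor` and whose
position carries a task-locked component (regressor × per-subject
amplitude). The variance modulation is what produces a positive task–FD
correlation: a purely positional task-locked term contributes FD only at
regressor *changes*, which cancel between block on- and offsets. Nuisance
channels are mixtures of a shared drift and a global AR(1) noise series.

What the generator does **not** emulate: physiological (cardiac or
respiratory) noise, spatial structure within ROIs or voxel-level
artifacts, distance-dependent motion artifacts, negative coupling between
networks, and behavioral responses. Passing tests therefore demonstrate
the pipeline's correctness and operating characteristics under a
well-specified signal model, not robustness to every artifact class in
real BOLD data.

A second, table-level generator (`simulate_summary_table()`) draws network
summary values directly — subject intercept (sd² 0.7) + network effect +
injected group × network effect + residual (sd² 0.3) — for the statistical
calibration and power studies. The 0.7 intraclass correlation at unit cell
variance reflects the high between-subject stability of connectome summary
measures; effect sizes passed to it are in within-cell sd units.

# Numerical choices and degenerate inputs

* HRF: double-gamma, response gamma shape 6 / rate 1, undershoot shape 16 /
  rate 1, ratio 6, sampled at TR, unit peak. No published parameterization
  accompanies the procedure this reimplements; these are the canonical
  values. The kernel vanishes at t = 0; its dense-grid argmax is 4.999 s
  (the undershoot nudges it marginally below the response gamma's mode at
  5 s).
* Boxcar sampling: a scan is "on" when its acquisition midpoint falls in a
  block — deterministic and slice-timing-agnostic. 27.5 s blocks at TR
  2.45 s contain 11 or 12 "on" scans.
* Correlation cap 1 − 1e-7 before atanh; weighted correlations with zero
  weighted variance are flagged undefined (NA) rather than silently zeroed,
  and adjacency construction refuses them naming the node pair.
* Thresholding tie-break: lexical (row, column) order after sorting by
  weight, making sweeps bit-reproducible across platforms.
* Rewiring: seeded; the caller's RNG state is restored; graphs with fewer
  than two edges are returned as copies with a warning.
* Sphericity on a singular contrast covariance reports W = 0 (boundary)
  with a warning; k = 2 gives epsilon = 1 identically. All-identical
  response values are a degenerate-input error everywhere in the battery.
* All interchange files carry 6 significant digits; re-running a pipeline
  configuration reproduces outputs bit-identically.

# Problem sizes

The test suite and the acceptance script size their studies as follows:
oracle comparisons run 100 random graphs (n ≤ 30) against igraph plus
brute-force enumeration; null-model ordering uses the 160-node pooled
static graph at cost 0.10 over 10 rewiring seeds; small-world screening
runs the full 30-cost efficiency grid with 100 rewiring attempts per edge;
type-I calibration uses 500 replicates at n = 18/18; effect recovery uses
200 replicates at n = 18/17 with a +1 within-cell-sd sensorimotor delta
for the patient group. End-to-end pipeline checks use cohorts of 4–8
participants at the full 260-volume, 160-node resolution.

# Known limitations

* The post hoc contrast of a 1-within-cell-sd group shift at n ≈ 18 per
  group has noncentrality ≈ 3.0 against a Tukey-adjusted critical value
  ≈ 2.6–2.7, so its power tops out near 0.6: with this design, reliably
  localizing an effect of that size to a specific network requires either
  a larger effect, more participants, or a less conservative family — the
  omnibus interaction, with power ≈ 0.95–0.99 under the same conditions,
  is the sensitive instrument.
* Group-level statistics on real cohorts of this size are sensitive to the
  covariate distribution; the covariate enters linearly and only through
  the strata described above.
* The packaged atlas's non-sensorimotor, non-cerebellar coordinates are
  synthetic stand-ins (the published per-network counts are respected);
  network membership, which is all the pipeline consumes, is faithful, but
  the x/y/z columns of those 109 nodes must not be interpreted spatially.
* Weighted-graph (non-binarized) metrics, community detection and other
  centralities are out of scope, as are voxel-level preprocessing and
  physiological noise modelling.
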