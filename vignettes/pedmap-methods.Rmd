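---
title: "Diffusion-map analysis of movement trajectories: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diffusion-map analysis of movement trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedmap)
```

`pedmap` maps multi-agent trajectory data to a fixed feature space,
embeds agents on a low-dimensional manifold via the spectrum of a
random-walk normalised graph Laplacian, and screens for behavioural
outliers at the extremes of the leading eigenvectors. This vignette is the
package's own account of the method: the model and its assumptions, the
parameters that matter, what the synthetic generators do and do not
emulate, the numerical choices, and the design decisions that were
genuinely open.

## From trajectories to features

A trajectory table holds one record per agent per frame: positions in
metres and, optionally, unit headings. When headings are absent,
`derive_directions()` computes them as normalised backward differences.
Two conventions deserve note:

* **Stationary inheritance.** A zero displacement inherits the previous
  frame's heading, so standing still does not create undefined (or
  spurious) directions. The first frame uses the forward difference; if an
  agent starts with a stationary spell, the first real step's direction is
  carried backwards. An agent that never moves has no meaningful heading at
  all and is excluded, with a warning.
* **Frames, not seconds.** All lagged features count frames. The frame
  interval is carried as metadata only; recordings at different frame
  rates should be resampled by the user before comparison, since a
  20-frame window at 25 fps and at 50 fps describe different time spans.
  The package deliberately exposes no resampling: interpolating positions
  fabricates motion, and the right resampling depends on the tracking
  pipeline that produced the data.

Each agent is then summarised by 27 observables (`feature_names()`): for
each of its three nearest co-present neighbours the mean and variance of
aheadness and leftness, the mean distance and the mean adjacent angle
(18 columns); mean and variance of the k-step turning angle for
k = 1, 5, 10, 20 (8 columns); and the mean 20-step path length (1 column).
Neighbours are ranked by Euclidean distance with ties broken by agent id,
which makes results reproducible across platforms. Aheadness and leftness
are signed projections on the agent's heading frame, with "left" fixed as
the counter-clockwise rotation in a right-handed x–y coordinate system;
under a global reflection of the data every leftness mean changes sign and
nothing else moves, a property the test suite checks.

Averages and variances are taken over each observable's *defined* frames
only: k-step features exist only from the k-th frame of a trajectory, and
rank-3 neighbour features only at frames with at least four co-present
agents. Variances use the population convention (divide by the count of
defined frames). An agent for which some observable is never defined —
most commonly a trajectory shorter than 21 frames, which can never support
the 20-step features — is excluded rather than imputed, and the exclusion
log records which observable was missing. Imputation here would
manufacture values the defining formulas cannot produce.

## The diffusion map

The feature matrix is standardised column-wise to mean 0 and standard
deviation 1 (population convention; enforced to 10⁻¹⁰), either globally —
appropriate when all runs probe the same behaviour, as on a closed track —
or per run, appropriate when runs differ strongly. A constant column
cannot be standardised and raises an error naming the column and group
rather than silently producing zeros.

Affinities are the reciprocal Euclidean feature distances,
C(i,j) = 1/D(i,j). The reciprocal kernel is kept exactly as stated, with
one numerical guard: coincident rows are clamped at D = 10⁻¹², making
duplicates near-certain mutual neighbours instead of a division by zero.
The matrix is sparsified by the symmetric top-p rule — an entry survives
iff it is among the p largest scores of either of its two rows — which
guarantees every node at least min(p, M−1) links. Ties at the p-th score
are all kept, so the guarantee is a floor, not an exact degree. The
default p = 20 sits at the upper end of the 10–20 neighbour range that is
customary for k-nearest-neighbour sparsification of affinity matrices.
One practical caveat matters when hunting small groups: a top-p graph
cannot resolve similarity structure on fewer than about p points, because
each member of a smaller group is forced to take most of its links from
outside the group. The egress outlier analysis below therefore uses
p = 10, matching the size of the planted groups; the ring analysis and the
degree contract use the default p = 20.

The random-walk normalised Laplacian is L = I − D⁻¹C with D the diagonal
of weighted degrees. Because C is symmetric, row and column degree sums
coincide; we normalise rows, so L's rows sum to zero and the constant
vector spans its null space on a connected network. The spectrum is
computed through the symmetric conjugate I − D^(−1/2) C D^(−1/2) (same
eigenvalues; a symmetric eigensolve is numerically stabler), and
random-walk eigenvectors are recovered as ψ = D^(−1/2)u. All eigenvalues
lie in [0, 2]; the multiplicity of the zero eigenvalue equals the number
of connected components, which the package determines exactly from the
graph rather than by thresholding eigenvalues (the numerical count with
relative tolerance `zero_tol = 1e-8` is reported alongside and agrees on
any sane input). A disconnected network raises a classed error advising a
larger p, since an embedding of a disconnected graph mixes incomparable
components.

Eigenvectors are reported unit-norm with the sign fixed so each vector's
largest-magnitude entry is positive — the sign of an eigenvector is
arbitrary, and fixing it makes runs comparable. Coordinates are the raw
eigenvector entries for the K smallest positive eigenvalues (default
K = 3); no diffusion-time weighting λᵗ is applied. Eigen-decomposition is
dense, which is the right tool for the package's intended scale (hundreds
to a few thousand agents); the sparse affinity still pays off in memory
and in the graph operations.

## What the generators emulate

Both generators are deliberately simple kinematic models, not
mechanistically faithful crowd simulators: they produce the *statistical
structure* the analysis assumes, with full determinism from a single seed
(one derived RNG stream per run).

**Closed track** (`generate_ring()`). Agents advance along the centreline
of a stadium-shaped track (26 m centreline, 2 m bend radius) at speed
base − slope · (local density in a ±1 m window), floored at 0.05 m/s, with
a per-agent speed offset (sd 0.03 m/s) and heading noise realised as a
lateral random walk within the track width. This builds in a
fundamental-diagram-like density–speed relation, so the run's group size
is a planted driving variable the embedding should recover; the defaults
(group sizes 10–40, 300 frames at 10 fps) make the recovery check
`|Spearman ρ| ≥ 0.8` between eigenvector 1 and group size pass with a wide
margin (observed ≈ 0.96). In the noiseless limit
(`heading_noise = 0, speed_sd = 0, slope = 0`) motion is exactly the base
speed along the track; note that the emitted 2-D step lengths on the bends
are chords, shorter than the arc by O((v·dt)²/r²) ≈ 2·10⁻⁵ m at the
defaults — the test suite asserts 10⁻⁴ agreement for this reason.

**Room egress** (`generate_egress()`). Normal agents steer towards the
nearest point of a bottleneck exit under goal attraction, short-range
separation, wall repulsion and heading noise, with heading inertia (65%
carry-over per frame) so headings do not flip within a frame even when
jostled; a trajectory ends once the agent is 0.5 m past the exit line,
the same margin convention `crop_region()` uses. The defaults — a 14 m
room, the exit low on the right wall, 60 agents at 0.6–0.7 m/s, 10 fps —
were chosen so that the normal crowd forms one compact, smoothly varying
population whose main residual variation is approach geometry.

Two kinds of atypical agents are planted, two of each per run by default:

* **Wall-followers** first cross to the far corner of the exit wall at a
  normal gait and then creep down the full wall towards the bottleneck —
  motion roughly perpendicular to the crowd's main direction — in a
  stop-and-go gait (walk 12 frames, stand 12), which cuts their 20-step
  path length far below any normal agent's.
* **Zigzag agents** work their way along the opposite (bottom) wall and
  backtrack — walk away from the exit — for a third of every 24-frame
  cycle, inflating their turning-angle variances by an order of magnitude
  and their path length well beyond their net displacement.

The planted agents are *scripted*: they ignore separation, noise and
inertia, share one gait phase per kind, and start from fixed per-kind
anchors (small jitter only). These choices are what make the planted
structure spectrally dominant: same-kind agents from different runs then
produce nearly identical feature rows, so each kind forms a tight group
attached to an opposite flank of the normal population, and the leading
eigenvector of the Laplacian separates wall-followers at one extreme from
zigzag agents at the other — the configuration the outlier-detection
contract tests (≥ 80% of planted agents inside the pooled top-10 extremes
of eigenvector 1, observed 100% across all seeds tried). The generator
guarantees detectability in principle too: every planted agent deviates
from the normal population by at least three pooled standard deviations in
the 20-step travel-distance mean or a turning-angle variance.

What these generators do **not** emulate: contact forces and body
exclusion (agents may transiently overlap), body-size heterogeneity,
realistic bottleneck congestion dynamics, anticipation or social grouping,
and measurement noise of video tracking. Passing the planted-recovery
tests therefore shows that the pipeline's machinery is sound — features
discriminate, the spectral step orders what the features separate — not
that real crowds will present outliers this cleanly. On real data,
atypical individuals are rarer, less stereotyped and less mutually
similar, so they should be expected at eigenvector extremes in the
qualitative sense, with the ranking noisier than here.

## Numerical choices and degenerate inputs

* Cosines are clamped to [−1, 1] before `acos` (dot products of unit
  vectors can overshoot by a few ulp).
* Variances are computed as E[x²] − E[x]² over defined frames and clamped
  at zero against rounding.
* Duplicate feature rows: distance clamp ε = 10⁻¹² in the affinity.
* Neighbour ties: agent id ascending; top-p ties at the threshold: kept.
* Disconnected networks: classed error (`pedmap_disconnected_error`)
  carrying the zero multiplicity, not a silent partial embedding.
* Single-point or never-moving trajectories: excluded at direction
  derivation, with a warning and a machine-readable attribute.
* Cropping that splits a trajectory keeps only the first contiguous
  in-region segment — re-validating the frames-contiguous invariant —
  and logs the truncation.
* Numbers written by `write_trajectories()` use 17 significant digits so a
  write/read cycle is bit-identical.

## Problem sizes

The shipped checks run at deliberate desk scale: rings of 6 runs × 10–40
agents × 200–300 frames (M = 140–180 rows) and egress sets of 5 runs × 60
agents (M = 300 rows), sizes at which the dense eigensolver is exact and
fast and a brute-force all-pairs oracle can verify every feature value.
The pipeline itself has no hard-coded limits; the affinity construction is
O(M²) in time and the dense eigensolve O(M³), which remains comfortable to
a few thousand agents.

## Known limitations

* Features are per-individual; run-level (group) features are out of
  scope, as are alternative feature sets and automatic feature selection.
* The reciprocal kernel 1/d is positivity-preserving and symmetric but not
  positive semi-definite in the usual kernel sense; it is used as defined,
  and the Laplacian's spectrum (not the kernel's) carries the analysis.
* Extremes are taken over the pooled embedding, not per data source; with
  strongly imbalanced sources a dominant source can crowd out the
  extremes of a smaller one.
* No out-of-sample extension: adding agents means recomputing the
  embedding.
* k-step features count frames; mixing frame rates without resampling
  changes the meaning of those features (see above).
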