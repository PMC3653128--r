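---
title: "Adaptive cluster analysis of MEG activation peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive cluster analysis of MEG activation peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apward)
```

## The problem

Beamformer source reconstruction turns MEG sensor recordings into
volumetric images of source power, expressed in pseudo-Z units (power
normalised by an estimated noise power, which removes the depth-dependent
gain bias of the spatial filter). A single such image localises activity
poorly: signal strength varies across frequency bands, and the spatial
extent of the reconstructed activity is broad. What *is* reliable is the
location of power peaks. When local maxima are extracted separately for
every experimental condition and frequency band and then pooled, peaks
reappear near genuinely active cortex over and over, while spurious peaks
scatter. The localization problem then becomes a spatial clustering
problem: find where peaks pile up consistently — within a subject across
conditions, and across subjects.

`apward` implements this post-processing chain:

1. **Peak extraction** — voxels that reach a band-specific pseudo-Z
   cutoff and strictly exceed all 26 neighbours; peaks from all
   conditions and bands are pooled per subject.
2. **Affinity Propagation (AP)** — exemplar-based partitioning of the
   pooled peak cloud; no cluster count needs to be chosen.
3. **Mesh analysis** — normalised peak density on a 1 mm cubic mesh;
   clusters denser than a gate (default 20%) are selected for
   refinement.
4. **Ward refinement** — a Ward dendrogram over each dense cluster is
   cut top-down so that every emitted sub-cluster has radius at most
   1 cm.
5. **Cross-subject consistency** — per reference region, each subject's
   nearest multi-peak cluster is matched; the region is *active* when
   the standard deviation of pooled member-to-centroid distances stays
   below 1 cm and every matched cluster has more than one peak.

## Parameters and their defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `band_thresholds` | 2 / 1.5 / 1 / 0.5 | pseudo-Z | cutoffs for alpha, beta, low gamma, high gamma; lower bands carry more power, so one shared threshold would bias extraction toward them |
| `density_gate` | 0.20 | fraction | normalised density above which an AP cluster is refined |
| `radius_max_mm` | 10 | mm | dendrogram-cut radius cap and the activity SD bound |
| `damping` | 0.5 | — | AP message damping λ |
| `convergence_tol` | 0.01 | fraction | relative message-change tolerance |
| `mesh_cube_mm` | 1 | mm | density mesh cube edge |
| `match_radius_mm` | 20 | mm | reference-matching radius |

The 1 cm radius cap bounds the localization precision from above; the
voxel size of the upstream beamformer grid (3 mm here) bounds it from
below. The gate trades reliability against detail: densities below ~20%
tend to come from peaks that do not repeat across conditions.

## Algorithmic choices that were genuinely open

**Similarity metric.** AP uses the *negative squared* Euclidean distance
between peak locations, the convention of the original exemplar-
clustering formulation; `metric = "euclidean"` is available as a config
switch. Self-preferences are the median of the off-diagonal
similarities, which gives every peak the same chance of becoming an
exemplar.

**AP degeneracy and convergence.** At an AP fixed point the exemplar
criterion $r(k,k)+a(k,k)$ is zero to machine precision for *every*
point, so its sign — and with it the exemplar set — would be decided by
rounding error. `affinity_propagation()` therefore follows the classic
reference implementation on three points: a deterministic perturbation
of the similarities at machine-epsilon scale; a stopping rule that
requires the exemplar set to be stable over 50 consecutive iterations
*in addition to* the 1% message-change tolerance; and a final refinement
of each exemplar to its cluster medoid. Without these, exemplar
identification on small inputs is essentially random (we measured 93/100
wrong exemplar sets on 3-point instances). On symmetric inputs AP can
oscillate indefinitely at λ = 0.5; the pipeline wrapper retries at
increased damping (up to 0.9) before accepting a degenerate result,
which is the remedy recommended by the algorithm's authors.

**What "radius" means.** The radius of a cluster is the *maximum*
member-to-centroid distance. This is the only definition under which
"every emitted cluster has radius ≤ r" is a hard guarantee of the
dendrogram cut, and the guarantee is property-tested. The standard
deviation of member-to-centroid distances is computed alongside, because
the activity criterion uses it.

**Dendrogram heights.** Ward merge heights are recorded as the increase
in within-cluster error sum of squares, ΔESS in mm². The merge structure
itself is computed by `stats::hclust(method = "ward.D2")`, whose heights
equal $\sqrt{2\,\Delta ESS}$ and are converted; `as.hclust()` exports a
tree on the conventional scale for standard dendrogram tooling. The
top-down radius cut replaces the manual trial-and-error search for a cut
point: a node is emitted as soon as it satisfies the radius cap,
otherwise its children are examined, so the emitted clusters always
partition the points.

**Cluster density.** The mesh assigns each cube `count / max(count)`.
How a *cluster* inherits a density is not canonical; the default is the
maximum over the cubes its members occupy, so that any cluster
containing a hot spot qualifies for refinement (`density_stat = "mean"`
is the alternative). Note that max-normalisation makes low densities
meaningful only when some cube genuinely accumulates many repeated
detections; with few peaks, every occupied cube trivially has a high
normalised density.

**Cross-subject matching.** The mapping from a subject's clusters to
named regions is reference-driven: each subject contributes its refined
cluster with the centroid nearest to the reference coordinate, if within
20 mm. Single-peak clusters are never matched — a lone stray detection
cannot represent a consistently active region, and letting it shadow a
genuine cluster nearby would veto the region for the whole group. The
activity SD pools member-to-centroid distances over all matched
subjects; per-subject SDs are reported alongside (the per-subject
reading of the criterion), with the pooled value decisive. Per-axis SDs
of the group mean use the n−1 denominator.

## The synthetic-data generator

Real multi-subject MEG peak tables are emulated by
`simulation_spec()` / `simulate_subject_peaks()`:

- regions are planted at fixed Talairach centres; each subject's centres
  are displaced by an isotropic Gaussian jitter (3 mm per axis by
  default), emulating anatomical variability;
- for every condition × band cell, peaks are drawn isotropic-Gaussian
  around the subject centre (4 mm per axis by default), so a region
  accumulates `peaks_per_condition × conditions × bands` detections;
- uniform background peaks are added per condition over a brain-sized
  bounding box;
- pseudo-Z values are drawn uniformly above the band threshold — they
  are deliberately nuisance variables, since only locations matter
  downstream.

The default scenario (`default_simulation_spec()`) plants the 13 bundled
literature regions with 2 peaks per condition × band over 12 conditions
and 4 bands — 96 peaks per region per subject, the same order of
magnitude as real per-cluster peak counts — plus 10 background peaks per
condition (~9% of the ~1400 peaks per subject). `simulate_volume()`
additionally builds 3 mm pseudo-Z volumes (Gaussian bumps plus white
noise) so the peak-extraction stage can be exercised end to end.

What the generator does **not** emulate: beamformer leakage and
correlated source cancellation, gyral/sulcal sensitivity differences,
condition-specific activation, non-Gaussian scatter, and the snapping of
peaks to the 3 mm reconstruction grid (simulated peak coordinates are
continuous). Passing tests on synthetic data therefore demonstrate the
correctness of the clustering chain under the assumed statistical
structure, not the fidelity of that structure to any particular MEG
data set.

## Numerical conventions

- Local maxima use strict inequality against all 26 neighbours; plateau
  voxels are not peaks, so constant regions yield none. Boundary voxels
  compete only against existing neighbours.
- Mesh cubes are half-open, `[i·c, (i+1)·c)` per axis, anchored at the
  Talairach origin: every point belongs to exactly one cube.
- Ties in argmax operations resolve to the lowest index; Ward merge ties
  are broken by `stats::hclust` (ties have measure zero for continuous
  coordinates).
- All simulation randomness derives deterministically from
  (`rng_seed`, subject index); the caller's RNG state is left intact.
- Degenerate inputs: a single point is its own exemplar; coincident
  points form one cluster; an all-constant volume has no peaks.

## Problem sizes used in the shipped checks

The test suite exercises AP against an exhaustive exemplar-subset search
at n ≤ 8 (the oracle is exponential), Ward against a brute-force greedy
ΔESS recomputation at n ≤ 7, and the full pipeline on the default
simulation: 10 subjects × ~1400 peaks, which runs in a few minutes. The
`scripts/acceptance.R` script reruns the default simulation at a
caller-supplied seed and recomputes the bundled group-to-literature
distances from the coordinate tables.

## Known limitations

- AP occasionally converges to a stable but suboptimal exemplar set
  (a few percent of small random instances, matching the behaviour of
  other AP implementations); the refinement stage downstream is robust
  to this, since over-split clusters are re-merged conceptually by
  region matching.
- With subject jitter of 3 mm, the group mean over 10 subjects carries
  roughly a 1 mm per-axis standard error relative to the nominal centre
  before any clustering error; sub-2 mm recovery of nominal centres is
  therefore at the edge of what the sampling noise permits.
- The activity criterion is a consistency screen, not a significance
  test; no null distribution is modelled.
- Region labels come entirely from the reference table; anatomical
  assignment of clusters far from every reference coordinate is out of
  scope.
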