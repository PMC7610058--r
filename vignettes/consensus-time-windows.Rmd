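---
title: "Multi-subject consensus clustering and ERP time-window detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-subject consensus clustering and ERP time-window detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A spatiotemporal ERP dataset is a matrix of time-points by electrodes: every
row is a scalp topography. During a stable cognitive operation the topography
changes little from sample to sample, so contiguous time-points with highly
similar maps mark the territory of one ERP component, and the borders of that
territory are a principled measurement time window for amplitude statistics.
Choosing such windows by eye is common practice and a known source of bias.

`erpconsensus` implements an objective alternative: cluster the topography
time series of *every* subject, combine the clusterings into one group-level
partition by consensus, and read the measurement window of each component of
interest off the winning cluster's span. The package contains the full
machinery — base clusterers, consensus and stabilization, window detection,
a calibrated simulator, and the statistical evaluation layer — and a thin
command-line wrapper (`inst/cli/erpconsensus.R`).

## The method

**Data model.** For each subject the per-condition epoch matrices
(time-points × channels, average reference) are concatenated in a fixed
condition order. In the canonical simulated study this gives 600 × 65 per
subject: two conditions of 300 samples at 429 Hz (−100…600 ms) over 65
electrodes.

**Base clusterers** (`run_base()`): Euclidean k-means, average-linkage
hierarchical clustering on `1 − r` with `r` the spatial (Pearson, across
channels) correlation, fuzzy c-means (fuzziness 2), a 1×k self-organizing
map, diffusion-map spectral clustering (Gaussian affinity at the median
pairwise distance, top-k eigenvector embedding), microstate *modified
k-means* (correlation assignment, mean or eigenvector templates, best of
several restarts by global explained variance), and AAHC
(atomize-and-agglomerate: repeatedly dissolve the cluster contributing least
GEV and reassign its members by spatial correlation). Correlation-based
methods see average-referenced rows; Euclidean methods raw rows; all
partitions are relabelled in first-occurrence order.

**Consensus (CSPA).** An ensemble of partitions is summarized by its
co-association matrix (fraction of partitions placing two time-points
together); the consensus is an average-linkage cut of `1 − coassociation`
at `k`. Average linkage was chosen as the graph-partitioning backend because
it is deterministic and dependency-free; the result is invariant to
relabelling of the members and idempotent on unanimous ensembles.

**Stabilization.** A stochastic clusterer is run `Mr` (default 20) times on
the grand average; `R_r` is the Rand similarity between the consensus of the
first `r` runs and the first `r − 1` runs. The chosen repetition count is
the smallest `r` with `max(|R_r − R_{r−1}|, |R_r − R_{r+1}|) ≤ eps` (0.03)
and `min(R_{r−1}, R_r, R_{r+1}) ≥ tau` (0.90). Repetition counts are
calibrated once on the grand average and reused for every subject; a flag in
`select_methods()`/`pipeline_config()` would let a user recompute per
subject, but per-subject calibration multiplies cost with no observed
benefit on simulated data.

**Method selection.** Every candidate method (stabilized if stochastic) is
compared per subject against the modified k-means benchmark with the Rand
index; candidates reaching `sim_threshold` (default 0.8) on at least half
the subjects join the consensus roster. The default roster offered to
selection for the simulated study is k-means, correlation hierarchical
clustering and AAHC; fuzzy c-means, SOM and diffusion spectral clustering
are implemented and selectable but are amplitude-driven on this class of
data and degrade the late P3 window border when forced into the ensemble.

**Two-level consensus.** Subject level: CSPA over the selected methods'
partitions of one subject's concatenated matrix. Group level: CSPA over the
subject partitions. Both use the same `k` (7 for the canonical study: six
components plus the pre-stimulus state).

**Window detection** (`detect_window()`): within one condition's slice,
every cluster intersecting the experimental measurement interval contributes
its longest intersecting run. A run qualifies if its *inner-similarity* —
the Fisher-z average of all pairwise spatial correlations of its time-points
— reaches `innsim_min` (0.90), its sample span reaches the minimum duration,
and it covers at least `min_overlap` (0.2) of the interval. Among qualifying
candidates the maximizer of `inner_similarity × overlap` wins; the reported
window is that cluster's run, not clipped to the interval.

**Evaluation.** Per-subject windows are compared to ground truth with
signed start/end/duration differences; Schuirmann's TOST (two one-sample t
tests, margin ±5 ms, α = 0.05, 90% CI reported) tests equivalence; mean
amplitudes inside the detected windows enter a balanced repeated-measures
ANOVA (within-only task design, or mixed 2×2 with a group factor);
`replicate_runs()` reruns the stochastic pipeline on fixed data and reports
the mean and SD of each effect's p value.

## The simulator

`simulate_study()` emulates a dipole-simulator study: six phasic components
(P1, N1, P2, N2, P3, N4) with focal Gaussian topographies on a synthetic
65-electrode unit-disc montage, raised-cosine-power envelopes, 20 subjects,
two conditions (condition 2 = condition 1 at gain 1.2, so N2/P3 amplitudes
are larger in condition 2), white Gaussian noise at 20 dB SNR calibrated on
each subject's whole concatenated dataset, and ±5 samples of latency jitter
applied per subject to the measurement-target components (shared across
conditions). A weak tonic background state (1 µV, own topography, plateau
over −100…48 ms) gives the pre-stimulus period a coherent map, matching the
observation that one of the seven cluster maps represents the pre-stimulus
brain state; without it the pre-stimulus segment is structureless noise and
no stable seventh cluster exists.

Choices a user should know about:

* **Decorrelated maps.** The component topographies are built as spatial
  Gaussians and then transformed so that all pairwise spatial correlations
  equal −0.1 (`decorrelate_topographies()`). Average-referenced focal maps
  are otherwise strongly correlated through the reference "seesaw" (up to
  0.75 for plausible layouts), which no clustering method can fully undo;
  spatially distinct dipolar sources — what a forward-model simulator
  produces — are far less correlated. The slightly negative target keeps
  between-component correlation distances above the noise–noise distance.
* **Envelope calibration.** N2 lives on 175–292 ms with peak 233 ms and a
  fall exponent of 1.3 (a mildly asymmetric deflection); P3 on 240–385 ms
  with peak 310 ms, symmetric. The signed-area fractions (0.89 for N2, 0.92
  for P3) were solved once from the closed-form envelopes so that the clean
  templates yield measurement windows of about 201–265 ms and 266–357 ms on
  the 429 Hz grid; `signed_area_window()` then recomputes these windows
  from the waveform at run time. Ground truth is computed from the clean,
  jitter-free templates and is invariant to noise level and jitter.
* **What is *not* emulated:** trial-level variability (the simulator works
  at the average-ERP level), realistic head geometry and volume conduction,
  non-Gaussian or temporally correlated noise, and between-subject
  topographic variability. Passing tests therefore demonstrate the
  machinery's correctness and its behaviour under calibrated noise and
  latency jitter — not performance on raw recordings.

## Numerical choices and degenerate inputs

* Sample `i` (0-based) sits at `epoch_start + i/sfreq·1000` ms; windows are
  closed intervals of sample times; all user-facing output is in ms.
* The duration filter counts a run of `m` samples as `m/sfreq` seconds (the
  inclusive span). The pipeline default minimum duration is 55 ms: the N2
  target window is itself only ~63 ms, so a 60 ms point-to-point filter
  would knife-edge the very component the interval targets whenever
  discretization trims one sample; 55 ms still rejects spurious fragments,
  which are an order of magnitude shorter. `detect_window()`'s own default
  stays at the conventional 60 ms.
* The minimum-overlap qualification (0.2) exists because a cluster run that
  barely grazes the measurement interval is not a usable measurement
  window; without it, a rare fragmented subject partition lets a
  neighbouring component's run win by inner-similarity alone. Failed
  detections are recorded as missing and excluded pairwise downstream.
* Inner-similarity averages correlations on the Fisher-z scale with
  clipping at `±(1 − 10⁻⁷)`. Averaging z-transformed *distances* instead
  (a literal reading of a distance-matrix formulation) is ill-posed for
  non-positive correlations, whose distances exceed 1; z-averaging the
  correlations reproduces `InnSim = 1 − D_avg` whenever `D = 1 − r`.
* Ties in assignments go to the lowest cluster id; empty k-means-family
  clusters are re-seeded from the worst-fit time-point; zero-variance rows
  correlate as 0 inside clusterers and raise errors in the user-facing
  similarity functions.
* TOST with zero-variance differences returns 0/0 or 1/1 by convention with
  a warning; a within-subject design with identical task columns returns
  `F = 0, p = 1`.

## Problem sizes in the shipped tests

The test suite exercises the canonical 20-subject 600 × 65 study once for
the end-to-end checks (component isolation, TOST equivalence), a reduced
8-subject version over 20 reruns for the robustness comparison against
single k-means (scaled from the 50 reruns a full study would use), and
10⁴ Monte-Carlo replicates for TOST calibration. Unit tests run on small
synthetic fixtures generated in code.

## Known limitations

* Group windows assume a shared epoch grid and condition order across
  subjects; no re-referencing or resampling is performed.
* The mixed ANOVA is restricted to balanced 2 × 2 designs (two levels need
  no sphericity correction); general factorial designs are out of scope.
* AAHC's dissolution criterion weights clusters by GFP × fit, so a genuinely
  low-amplitude state can be dissolved before a high-amplitude one — the
  classical behaviour of the algorithm, visible here if component
  amplitudes are made very unequal.
* `choose_k()` scores k by mean `inner-similarity × overlap` of the
  detected windows — a pragmatic stand-in for a full cluster-number
  criterion, adequate for scanning a handful of candidate k values.
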