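# erpconsensus

Multi-subject consensus clustering of spatiotemporal ERP data and
data-driven detection of component measurement time windows.

## The problem

Event-related potential (ERP) statistics — mean amplitudes, latency
comparisons across conditions or groups — depend on the *measurement time
window* chosen for each component, and that choice is usually made by eye.
Every row of an ERP epoch matrix (time-points × electrodes) is a scalp
topography, and during one cognitive operation the topography is
quasi-stable; the span of time-points sharing one topography is therefore a
principled, reproducible window for the component expressed there.

`erpconsensus` finds those spans by clustering the topography time series of
*every subject*, not just the grand average:

1. **Base clusterings.** Each subject's concatenated condition matrix
   (e.g. 600 × 65: two conditions × 300 samples at 429 Hz × 65 electrodes)
   is partitioned by several clusterers used in EEG microstate analysis —
   microstate *modified k-means*, AAHC, correlation-based hierarchical
   clustering, k-means, fuzzy c-means, 1-D SOM, diffusion-map spectral
   clustering.
2. **Stabilization.** Each stochastic clusterer is repeated and replaced by
   the CSPA consensus of its runs; the repetition count `r` is chosen where
   the Rand similarity `R_r` between consecutive consensus partitions
   satisfies `max(|R_r − R_{r−1}|, |R_r − R_{r+1}|) ≤ 0.03` and
   `min(R_{r−1}, R_r, R_{r+1}) ≥ 0.90`.
3. **Method selection.** Candidates are kept when their Rand similarity to
   the modified k-means benchmark reaches 0.8 for at least half the
   subjects.
4. **Two-level consensus (CSPA).** Subject level: consensus over the
   selected methods' partitions; group level: consensus over the subject
   partitions. CSPA = average-linkage clustering of `1 − coassociation`,
   where the co-association matrix holds the fraction of partitions placing
   two time-points together.
5. **Window detection.** Within a condition, each cluster intersecting the
   experimental interval contributes its longest run; runs qualify by
   *inner-similarity* (Fisher-z mean pairwise spatial correlation ≥ 0.90),
   duration and interval coverage, and the best `inner-similarity ×
   overlap` run is the measurement window.
6. **Evaluation.** TOST equivalence of per-subject windows against ground
   truth (±5 ms margin), repeated-measures / mixed 2 × 2 ANOVA of mean
   amplitudes, and robustness (mean/SD of p values) over repeated runs.

Because real multi-subject recordings of this kind are not publicly
available, the package ships a calibrated simulator
(`simulate_study()`): six components (P1, N1, P2, N2, P3, N4) with distinct
topographies on a 65-electrode layout, 20 subjects, two conditions, white
Gaussian noise at 20 dB SNR and ±5 samples of latency jitter, plus
signed-area ground-truth windows computed from the clean templates.

## Worked example

```r
library(erpconsensus)

# canonical simulated study: 20 subjects, 2 conditions, 600 x 65 each
study <- simulate_study(study_spec(seed = 1))

# ground-truth signed-area windows of the clean N2 / P3 templates
study$ground_truth$Cond1
#> $N2
#> [200.70, 263.64] ms (duration 62.94 ms)
#>
#> $P3
#> [268.30, 356.88] ms (duration 88.58 ms)

res <- run_pipeline(study, pipeline_config(seed = derive_seed(1, "pipeline")))
res$group_windows[, c("condition", "component", "start_ms", "end_ms",
                      "inner_similarity")]
#>   condition component start_ms   end_ms inner_similarity
#> 1     Cond1        N2 200.6993 261.3054        0.9891676
#> 2     Cond1        P3 263.6364 356.8765        0.9873708
#> 3     Cond2        N2 200.6993 261.3054        0.9901344
#> 4     Cond2        P3 263.6364 356.8765        0.9878784

subset(res$tost, property == "start",
       c(component, condition, p1, p2, mean_diff, equivalent))
#>    component condition           p1           p2  mean_diff equivalent
#> 1         N2     Cond1 4.618426e-11 1.036824e-08  0.8158508       TRUE
#> 4         N2     Cond2 4.618426e-11 1.036824e-08  0.8158508       TRUE
#> 7         P3     Cond1 1.013766e-02 2.973523e-06 -2.0979021       TRUE
#> 10        P3     Cond2 7.364643e-03 2.917385e-06 -1.9813520       TRUE
```

The detected group windows sit within one to two samples (2.3-4.7 ms) of
the ground-truth windows; the per-subject windows are statistically equivalent
to ground truth within ±5 ms (both TOST nulls rejected), and the group
partition at `k = 7` isolates all six planted components plus the
pre-stimulus state (`component_isolation(res$group_partition, study)`).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/erpconsensus.R simulate --subjects 20 --seed 1 --out study/
Rscript inst/cli/erpconsensus.R run --study study/ --k 7 --seed 1 --out results/
```

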