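# fnirsnet

Graph-theoretic analysis of prefrontal fNIRS functional connectivity under a
cognitive task, built for studies of post-stroke depression (PSD).

## The problem

About a third of stroke survivors develop depression, and its diagnosis
still rests on symptom scales such as the 24-item Hamilton Depression Rating
Scale (HAMD ≥ 8 defines the depressed group here). A candidate objective
marker is the topology of the dorsolateral-prefrontal (DLPFC) functional
network measured with functional near-infrared spectroscopy (fNIRS) while
the brain is engaged by an auditory oddball task — rare "deviant" target
tones (25%) embedded in frequent standards — rather than at rest. The
working hypothesis: network alterations associated with PSD are more
pronounced, and discriminate patients better, in the task state than in the
resting state.

`fnirsnet` implements that analysis end to end for a 14-channel bilateral
DLPFC montage (7 sources, 6 detectors, 3 cm separation, 11 Hz, wavelengths
730/808/850 nm), together with a forward simulator that generates fully
synthetic cohorts with known ground truth so every stage is testable
without any recorded data.

## What it computes

* **Preprocessing** — raw intensity → optical density
  (OD = −log₁₀ I/I₀); motion-artifact detection in consecutive 0.5-s
  windows flagged when the OD range exceeds 6× the whole-trial SD, with
  cubic-spline reconstruction; zero-phase Butterworth band-pass
  0.01–0.2 Hz; modified Beer–Lambert inversion
  ΔOD(λ) = [ε_HbO(λ)ΔHbO + ε_HbR(λ)ΔHbR]·d·DPF solved by least squares
  over the three wavelengths (d = 3 cm, DPF = 6).
* **Connectivity** — Pearson correlation of the HbO series of all 91
  channel pairs per state (rest = 20-s baseline, task = 360-s oddball
  block), Fisher-z transformed (z = atanh r); negative entries zeroed and
  binarized at sparsity thresholds 0.15–0.50 in steps of 0.05
  (K = ⌊s·N(N−1)/2⌋ strongest edges).
* **Graph metrics** — per threshold: clustering Cp/NCp, characteristic path
  length Lp, small-world Gamma, Lambda, Sigma = Gamma/Lambda against 100
  degree-preserving rewired surrogates, efficiencies Eg/Eloc/Ne/NLe, degree
  Dc, betweenness Bc, assortativity r, hierarchy b (C ∝ k^−b); each metric
  summarized by its trapezoidal AUC across the sweep.
* **Group statistics** — Shapiro–Wilk-gated two-sample t / Kruskal–Wallis
  comparisons edge-wise (91 tests) and metric-wise (79 AUC features),
  Fisher's exact test for categorical demographics, Spearman correlation of
  pooled metric values with HAMD scores.
* **Classification** — the 79 AUC features (9 global + 5 nodal × 14
  channels) per state feed a cost-sensitive linear SVM (class weights ∝
  inverse class frequency) with fold-internal standardization and PCA (95%
  variance), under stratified 8-fold cross-validation repeated 10 times.

The simulator plants a configurable group effect in the inter-channel
covariance (task state: weakened coupling of the mid-frontal channel 7 with
the lateral channels plus elevated local clustering in the depressed group;
rest state: elevated (4,6)/(2,5) coupling) on top of an HRF-convolved
oddball response, band-limited covariance-structured noise, physiological
nuisance (cardiac 1.2 Hz, respiration 0.25 Hz, Mayer 0.1 Hz, drift) and
spike/shift motion artifacts.

## A worked example

```r
library(fnirsnet)

cfg <- default_config(seed = 1)      # 19 PSD vs 18 non-PSD, effect size 1
analysis <- run_pipeline(cfg)
print(analysis)
```

```
fNIRS brain-network analysis
  cohort: nonPSD=18, PSD=19
  rest: 1 significant edges, 1 significant metric AUCs, accuracy 43.24% +/- 6.98%
  task: 18 significant edges, 9 significant metric AUCs, accuracy 68.92% +/- 2.30%
```

Reading the output: in the resting state (a 20-s baseline, hence very noisy
connectivity estimates) the two groups are barely distinguishable — about
as many significant tests as expected by chance at α = 0.05 and
cross-validated accuracy near the 50% chance level. In the task state the
planted network effect is visible: the edges linking the mid-frontal
channel to lateral channels and the metric AUCs they drive (efficiency,
clustering, path length) separate the groups, and the same 79 features
classify depressed vs non-depressed subjects clearly above chance
(68.9% ± 2.3% vs 43.2% ± 7.0%). That task-over-rest contrast is the
pipeline's headline result structure.

`summary(analysis)` lists the significant edges and metrics;
`run_pipeline(cfg, out_dir = "run1")` archives every table (connectivity
matrices, metric sweeps, statistics, classification reports) as CSV/JSON
beside the configuration and its MD5 hash.

## Package layout

| Area | Files |
|---|---|
| Synthetic cohorts | `R/schedule.R`, `R/montage.R`, `R/covariance.R`, `R/simulate.R` |
| Preprocessing | `R/preprocess.R`, `R/mbll.R` |
| Connectivity & graphs | `R/connectivity.R`, `R/graphmetrics.R` |
| Statistics & classification | `R/groupstats.R`, `R/classify.R` |
| Orchestration & I/O | `R/pipeline.R`, `R/io.R` |

The methods vignette (`vignettes/fnirs-network-analysis.Rmd`) documents the
forward model, every tunable parameter with units and defaults, the
numerical conventions (rounding, tie-breaks, clipping, degenerate cases)
and the validation design.
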