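---
title: "Brain-network analysis of oddball-task fNIRS: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-network analysis of oddball-task fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Post-stroke depression (PSD) is the most common neuropsychiatric complication
of stroke, conventionally diagnosed with symptom scales such as the 24-item
Hamilton Depression Rating Scale (HAMD; a score of at least 8 defines the
depressed group here). A candidate objective marker is the topology of the
prefrontal functional network measured with functional near-infrared
spectroscopy (fNIRS) while the brain is engaged by a cognitive probe — the
classic auditory oddball task — rather than at rest. `fnirsnet` implements
that analysis end to end: a bilateral dorsolateral-prefrontal (DLPFC) montage
of 14 channels sampled at 11 Hz, a 20-s rest baseline followed by a 360-s
oddball train (tones of 0.05 s, inter-stimulus jitter 1–3 s, 25% rare
"deviant" targets), preprocessing of raw optical intensity to oxygenated
hemoglobin (HbO), Fisher-z Pearson connectivity per state, binary graph
metrics across a sparsity sweep, group statistics, and PSD/non-PSD
classification.

Because no recorded cohort ships with the package, a forward simulator with
known ground truth is a first-class module: every downstream stage is
validated against data whose generating process is known exactly.

## The forward model

For each subject the HbO series of channel $i$ is

$$x_i(t) = c_i\, h(t) * u(t) \;+\; \eta_i(t) \;+\; \nu_i(t) \;+\; d_i t,$$

* $u(t)$ — the stimulus impulse train; deviant tones carry amplitude
  0.8 µM, standards 0.4 µM (deviants are attended targets and evoke the
  larger response). $h$ is the canonical double-gamma hemodynamic response
  (peak 6 s, undershoot ratio 1/6) — the source publication's pipeline never
  models hemodynamics explicitly; the HRF exists only to make task data
  realistic. $c_i$ is a fixed spatial loading peaking at the mid-frontal
  channels.
* $\eta(t)$ — band-limited (0.01–0.2 Hz) multivariate Gaussian fluctuations
  with per-channel SD 0.5 µM. Their inter-channel covariance is the planted
  ground truth: the rest segment draws from the rest-state profile, the task
  segment from the task-state profile. Band-limited series are synthesized
  spectrally (white noise transformed to the frequency domain, out-of-band
  bins zeroed, power renormalized), which preserves the planted cross-channel
  correlation exactly and makes Monte-Carlo experiments cheap. A consequence
  worth knowing: with a 0.2 Hz bandwidth the 3960-sample task segment carries
  an effective sample size of roughly $2 B T \approx 140$, so single-subject
  correlations scatter with SD ≈ 0.08 around their planted values.
* $\nu(t)$ — sinusoidal physiological nuisance: cardiac 1.2 Hz (0.15 µM),
  respiratory 0.25 Hz (0.10 µM), Mayer waves 0.10 Hz (0.03 µM), with
  per-channel random phase and ±5% per-subject frequency jitter, plus a
  linear drift (0.1 µM over the recording). Cardiac and respiration lie
  outside the 0.01–0.2 Hz analysis band on purpose, so the band-pass stage
  is testable; the Mayer component lies inside the band and is kept small
  for that reason.

Deoxygenated hemoglobin is modeled as $-0.35\,x$ plus small independent
fluctuations; raw intensity at 730/808/850 nm follows the forward modified
Beer–Lambert law (below) from a nominal source level, with optional motion
artifacts added in optical-density space: half-sine *spikes* (0.4 s,
10× the clean trial SD) and boxcar baseline *shifts* (3–8 s, 8× SD).
Artifact amplitudes are expressed in trial-SD multiples so their relation to
the 6-SD detection rule is unambiguous.

### The planted group effect

`generate_group_covariance()` builds one correlation profile per group and
state on a common baseline (stronger within a hemisphere, decaying with
channel distance, weaker across hemispheres, homologous pairs elevated). The
depressed-group profiles deviate by `effect_size`:

* task state — coupling of the mid-frontal channel 7 with the lateral
  channels 1, 3, 4, 10, 11, 13, 14 reduced by `0.30 * effect_size`, and
  adjacent within-hemisphere lateral pairs raised by `0.12 * effect_size`.
  The two components together weaken integration through the mid-frontal
  hub while raising local clustering, which is exactly the qualitative
  signature reported for depressed networks under task (lower global
  efficiency and hierarchy, higher clustering, path length, local
  efficiency and assortativity).
* rest state — pairs (4,6) and (2,5) raised by `0.25 * effect_size`.

At `effect_size = 0` all four profiles are identical, which is the basis of
the null-calibration experiments. Planting is followed by an eigenvalue
check; an indefinite matrix is projected to the nearest positive
semidefinite correlation matrix with a warning.

### What the simulator does not emulate

Real fNIRS data add scalp/skull partial-volume effects, short-separation
systemic physiology, motion-coupled optode decoupling, non-Gaussian and
nonstationary background fluctuations, and between-subject anatomical
variability. Passing tests on synthetic cohorts therefore demonstrate that
the *pipeline* is correct and calibrated, not that the clinical effect
sizes of any particular study generalize.

## Preprocessing

The stages run in a fixed order (the driver records the order and a property
test asserts it): optical density → artifact correction → band-pass →
Beer–Lambert inversion.

1. **Optical density.** $OD(t) = -\log_{10} I(t)/I_0$ per channel and
   wavelength, $I_0$ the whole-recording mean intensity (a rest-baseline
   mean is available by option). Non-positive intensities are an error that
   names the channel and sample.
2. **Motion artifacts.** The recording is tiled into consecutive
   non-overlapping 0.5-s windows (`round(0.5 * fs)` = 6 samples at 11 Hz; a
   trailing partial window of at least 2 samples is kept). A window is
   flagged when its OD range (max − min) exceeds 6× the SD of the whole
   trial, at any wavelength. The trial SD is computed on the raw OD before
   any correction, per channel and wavelength. Flagged samples are
   re-estimated by a natural cubic spline through all clean samples of the
   channel; flagged stretches at the recording edges use nearest-value fill
   (and are logged), since a spline would extrapolate there. Sustained
   baseline shifts are only partially correctable by this rule — the
   transitions are flagged but the plateau is not — which mirrors the
   behavior of the windowed-range method itself.
3. **Band-pass.** Zero-phase forward–backward Butterworth (order 3 per
   pass) between 0.01 and 0.2 Hz. The series is demeaned and padded by odd
   reflection (one low-cutoff period) before filtering to suppress the slow
   startup transient. Recordings shorter than three periods of the low
   cutoff are rejected with advice to filter a longer segment.
4. **Beer–Lambert inversion.** At each wavelength
   $\Delta OD(\lambda) = [\varepsilon_{HbO}(\lambda)\Delta HbO +
   \varepsilon_{HbR}(\lambda)\Delta HbR]\, d\, DPF$ with source–detector
   separation $d = 3$ cm and DPF 6.0 at all wavelengths (configurable; the
   instrument convention is not published, so a standard flat DPF is used).
   The 3×2 system over the three wavelengths is solved by least squares —
   all three wavelengths are used rather than a pair, again because the
   instrument's own choice is not published. Extinction coefficients come
   from the standard compilation of hemoglobin spectra
   (`extinction_coefficients()`), in cm⁻¹ M⁻¹.

## Connectivity and binary networks

Rest is `[0, 20)` s and task `[20, 380)` s — 220 and 3960 samples. The
20-s baseline is statistically thin for 0.01-Hz-filtered data (an effective
sample size near 8), so rest-state connectivity estimates are intrinsically
noisy; the simulator exposes `rest_duration_s` so longer baselines can be
generated, but the default stays at 20 s to match the study design.

Connectivity is the Pearson correlation between the HbO series of all 91
channel pairs, Fisher-z transformed with $|r|$ clipped at $1 - 10^{-7}$ so
`atanh` stays finite. The transform is applied to $r$ first and negatives
are zeroed afterwards — sign-equivalent to zeroing negative $r$, since
`atanh` preserves sign. Binarization keeps the
$K = \lfloor s\,N(N-1)/2 \rfloor$ strongest positive weights at sparsity
$s \in \{0.15, 0.20, \dots, 0.50\}$ (so $K = 13 \dots 45$ at $N = 14$).
Rounding is `floor` and ties break by ascending channel-pair lexicographic
order, both chosen for exact reproducibility. If fewer positive weights
exist than requested, all positives are kept and a warning logged.

## Graph metrics

All metrics are implemented from first principles on the binary adjacency
matrix and verified against brute-force oracles (Floyd–Warshall distances,
exhaustive triangle counts, path-counting betweenness, closed-form OLS) and
against igraph as an independent implementation:

* degree centrality `Dc`; nodal clustering `NCp` with
  $NCp_i = 2t_i / k_i(k_i-1)$ and 0 for $k_i < 2$; `Cp` = mean over all
  nodes;
* shortest paths by BFS; characteristic path length `Lp` averages over
  *connected* ordered pairs (disconnected graphs are inevitable at sparsity
  0.15); global efficiency `Eg` and nodal efficiency `Ne` assign
  $1/\infty = 0$ — both standard conventions;
* nodal local efficiency `NLe` is the global efficiency of the subgraph
  induced by a node's neighbors (0 for degree < 2); `Eloc` = mean `NLe`;
* betweenness `Bc` by Brandes' algorithm, unnormalized (group comparisons
  are scale-invariant; normalization can be applied downstream);
* assortativity `r` is Newman's degree–degree correlation over edge
  endpoints, undefined (NA) for regular graphs;
* hierarchy `b` is minus the OLS slope of $\log NCp$ on $\log Dc$ over
  nodes with degree ≥ 2 and $NCp > 0$ (the log–log regression domain),
  undefined with fewer than two eligible nodes or no degree variance —
  the $C \propto k^{-b}$ convention of the standard network toolboxes;
* the small-world triple uses degree-preserving double-edge-swap surrogates
  (100 per threshold by default, at least 10 swaps attempted per edge,
  seeded): `Gamma` = `Cp`/mean reference `Cp`, `Lambda` = `Lp`/mean
  reference `Lp`, `Sigma` = `Gamma`/`Lambda`. Connectedness of surrogates
  is not enforced.

Each metric's curve over the 8 thresholds is integrated by the trapezoidal
rule into its AUC, the threshold-free summary used for statistics and
classification (a constant curve $v$ gives $0.35\,v$). A missing value at
any threshold propagates to a missing AUC with a recorded reason; missing
AUCs are median-imputed (and logged) at feature assembly.

## Group statistics

`compare_groups()` gates on Shapiro–Wilk normality (α = 0.05) in both
groups: a two-sample pooled-variance t-test when both pass, otherwise the
Kruskal–Wallis rank test (with two groups, a two-sided rank-sum test). The
edge-wise comparison runs one test per channel pair (91 at $N = 14$),
uncorrected by default — multiple-comparison correction is deliberately
omitted to mirror common practice in this literature, with
Benjamini–Hochberg available behind `fdr = TRUE`.

One point deserves emphasis. A one-tailed test whose direction is chosen
from the observed sample means has twice its nominal level — under the null
it rejects 10% of the time at α = 0.05. The package therefore screens with
two-sided tests by default, which is what makes the null-calibration
experiments meaningful; `tails = "one"` is available and every record
states the tested direction explicitly ("A>B"/"B>A") so directional
reports remain interpretable. Spearman correlations with HAMD pool both
groups into one set and use midranks with a two-sided p-value.

## Classification

The 79 features per state (9 global + 5 nodal × 14 channel AUCs, canonical
column order) feed a cost-sensitive support vector machine evaluated by
stratified 8-fold cross-validation repeated 10 times. Strictly inside each
training fold the features are standardized and projected onto the
principal components retaining 95% of the variance; fitting the projection
on all subjects before splitting would leak test information into training,
so the leak-free variant is the default. Class weights are inversely
proportional to the training-fold class frequencies (the cost-sensitive
formulation with no published weights), the kernel is linear by default
with RBF behind a flag, and folds are stratified so a 37-subject cohort
splits into folds of 4–5. Accuracy is the fraction of correctly identified
subjects; the report carries per-fold accuracies and mean ± SD over
repeats.

## Validation design and problem sizes

The test suite validates each module against oracles and the pipeline
against its own ground truth at these sizes, chosen to give stable Monte
Carlo estimates on a single CPU:

* 200 random 8–14-node graphs for metric-oracle equivalence at 1e-10;
* 100 rewired surrogates for small-world sanity (ring lattice vs
  Erdős–Rényi);
* 50 seeds for the convergence of noise-only sample correlations to their
  planted values (±0.05 on the mean);
* 200 null cohorts (19 vs 18, `effect_size = 0`) for type-I calibration:
  the significant fraction of edge-wise and metric-wise tests must fall in
  the 95% binomial band around α at the cohort count,
  $0.05 \pm 1.96\sqrt{0.05 \cdot 0.95 / 200}$ — the cohort-level band is
  used because tests within a cohort are correlated;
* 50 cohorts with a task-state-only plant for the headline contrast: more
  significant effects and higher classification accuracy in task than rest
  in at least 90% of cohorts.

## Known limitations

* Rest-state quantities inherit the 20-s baseline's tiny effective sample
  size; treat rest-state group maps as exploratory (or lengthen the
  simulated baseline).
* Sustained baseline shifts survive the windowed-range artifact rule in
  attenuated form; the rule is faithful to its definition, not optimal.
* HbR is propagated through the optics but not analyzed downstream; the
  analysis is HbO-only by design.
* Graph metrics are binary and undirected; weighted, directed, modular and
  rich-club variants are out of scope.
* The classifier does no hyperparameter search; it evaluates the fixed
  cost-sensitive linear SVM of the study design.

## A minimal run

```{r example}
library(fnirsnet)

cfg <- default_config(seed = 1)
analysis <- run_pipeline(cfg, verbose = TRUE)
print(analysis)
summary(analysis)

# archive all tables beside the configuration and its hash
run_pipeline(cfg, out_dir = "fnirsnet-run")
```
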