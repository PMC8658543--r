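---
title: "From calcium movies to network refinement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From calcium movies to network refinement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arcnet)
```

## The problem

Dissociated hippocampal cultures respond to a chemical long-term-potentiation
cocktail (4-aminopyridine + bicuculline + forskolin) with a paradoxical
combination: single-neuron firing rates rise while pairwise correlated firing
falls on average, yet a small subset of neurons *increases* its mutual
correlation. This selective restructuring — a global decrease with a retained
high-correlation core — is called **refinement**, and the immediate-early
genes Arc and c-Fos mark the neurons involved. `arcnet` implements the full
analysis chain needed to quantify this phenomenon from raw inputs: nuclear
segmentation and marker thresholding, calcium-trace correction and spike
deconvolution, spike-time correlation networks, the Intrinsic Connectivity
Distribution (ICD) refinement metrics, and the cohort-level regression that
links Arc expression to network state. A ground-truthed synthetic-culture
generator makes every stage testable without any experimental data.

## Marker thresholding

Marker intensity over a culture is bimodal: a negative population and a
positive one. `fit_two_normal_mixture()` fits the two-component normal
mixture by EM (initialized by a median split; convergence when the
log-likelihood improves by less than 1e-6, at most 500 iterations; the
log-likelihood trace is retained because its monotonicity is a correctness
check). The positivity threshold is `mu_neg + 3 * sigma_neg` — a cell counts
as positive only above 99.7% of the negative population — with a strict
inequality; ties sit on a measure-zero boundary. Thresholds are fitted
**per culture**, since staining intensity scales vary between preparations.
Two degenerate cases are handled explicitly: constant input is an error, and
a collapsed fit (component means within one SD) is warned about; inside
`run_pipeline()` a collapsed channel is interpreted as "no separable positive
population" and every cell is scored negative for it. Only NeuN-positive
ROIs enter any neuron-level analysis; Arc/c-Fos combinatorial groups
(`Arc+cFos+`, `Arc+cFos-`, `Arc-cFos+`, `Arc-cFos-`) are defined on that
subset.

Segmentation of the nuclear channel is deliberately simple and swappable:
global Otsu threshold, connected components, area filter `[50, 5000]` px, no
watershed splitting of touching nuclei. The synthetic fixtures render
non-touching disks, so a more elaborate recipe would only add moving parts
that this analysis cannot validate. Pixel coordinates are 0-based with
x = column, y = row; the imaging field is 1007 × 1007 px at 0.8 µm/px
(0.64 mm²).

## Trace correction and dF/F

The background and photobleaching correction uses the cells that were silent
during the recording: the lowest tenth percentile of cells ranked by the
temporal variance of their raw trace (variance is the natural proxy for
"silent"). Their mean value at each time point is subtracted from every
trace, removing the shared background and bleach component. The published
description of this step calls the subtracted signal "ΔF/F" even though it
is a pure subtraction; `correct_and_normalize()` therefore supports both
readings. The default (`mode = "dff"`) follows the field's convention and
divides by a baseline, `(F - b(t) - F0) / F0`, with `F0` the per-cell 10th
percentile of the background-subtracted trace; `mode = "subtract_only"`
reproduces the literal subtraction. Cells whose `F0` is not positive —
notably the silent reference cells themselves, whose subtracted trace is
~0 — are left unscaled and flagged, rather than divided by a vanishing
baseline.

## Spike inference

`infer_spikes()` maximizes the standard fast-oopsi posterior: AR(1) calcium
`C_t = gamma * C_{t-1} + n_t`, Gaussian observation noise, an exponential
(sparsity) prior on the nonnegative per-frame spike mass. The solver is
projected coordinate descent on the spike variables — each update is an
exact one-dimensional quadratic solve projected onto `n_t >= 0`, so the
objective decreases monotonically and convergence is declared when the
largest coordinate move in a sweep falls below tolerance (failure to
converge is an error carrying diagnostics, not a silent result).

Defaults, all overridable:

* `gamma = exp(-0.2)` ≈ 0.82 — a 1 s calcium decay time imaged at 5 Hz;
* noise SD estimated robustly as `mad(diff(trace)) / sqrt(2)`;
* sparsity weight `lambda = 4 * sigma * sqrt(sum(gamma^(2k)))`: on a
  ~300-frame trace this ~4 SD (Bonferroni-scale) bound makes spurious
  supra-threshold excursions from white noise alone essentially impossible,
  and in the package's own simulations at SNR 10 it leaves spike-count
  estimates unbiased;
* spike discretization at 0.1 × the maximum inferred mass, with runs of
  consecutive supra-threshold frames collapsed to their mass-maximal frame
  (a spike near a frame boundary legitimately spreads over two frames).

The inference is approximate by construction: it is not calibrated to
action-potential counts, and recovery is validated only against the
package's own forward model (noiseless impulses are localized exactly; at
SNR 10, 5 Hz and 0.2 Hz spiking the detection F1 exceeds 0.8 and the median
relative rate error stays below 25%).

## Spike-time correlation (STTC) networks

Pairwise correlation uses the spike time tiling coefficient with
`Delta-t = 50 ms`:

$$\mathrm{STTC} = \frac{1}{2}\left(\frac{P_A - T_B}{1 - P_A T_B} +
\frac{P_B - T_A}{1 - P_B T_A}\right)$$

where `T` is the fraction of recording time within ±Δt of a train's spikes
(tiles clipped at the recording boundaries, overlaps merged) and `P` the
fraction of one train's spikes within ±Δt of the other's. The measure is
insensitive to firing rate — a property the tests verify on independent
Poisson pairs at 10-fold different rates — and equals +1 for identical
non-degenerate trains. An STTC value between a pair is the analysis'
correlation index (CI). Undefined pairs (an empty train, or a degenerate
denominator) are stored as missing and excluded from means and change
classification, contributing 0 to node strengths; fabricating zeros into
means would bias every group summary. The diagonal is excluded everywhere.
Negative CI values are retained in means and total flow (the network is
undirected and anticorrelation is information), but floored at zero for the
ICD analysis below, where the survival curve of a signed quantity would be
ill-posed.

Correlation-change classification between baseline and after-stimulation
matrices uses the band rule: **positive-change** pairs move from
`[0, 0.5)` to `[0.5, 1]`, **negative-change** pairs make the mirrored move.
(The published verbal definition repeats the positive intervals for the
negative class — an evident transcription slip; the mirrored rule is the
only self-consistent reading and matches the accompanying figure's
description.) Arc-pair fraction curves qualify positive-change pairs by
their final CI and negative-change pairs by their initial CI.

## The ICD refinement metrics

Setting a single CI threshold to find "the high-CI subset" would not
transfer across cultures. The ICD avoids that: node strengths (total flow,
negatives floored) are normalized to `[0, 1]` by `n - 1`, their survival
curve `d(tau)` (fraction of nodes with normalized strength above `tau`) is
fitted with a stretched exponential

$$d(\tau) = e^{-\alpha\,\tau^{\beta}}$$

(bounded Levenberg-Marquardt, initialized at α = β = 1, on a 101-point
grid over `[0, 1]`), and two epochs are compared by the **difference of the
fitted curves**, baseline minus after, so that a global CI decrease yields
a positive peak. Differencing the fits rather than the raw curves smooths
the comparison; both the subtraction order and a raw-curve option are
exposed because neither is forced by the method itself. The difference
curve is summarized by peak height, peak location, width at half peak
height (outermost half-height crossings, linearly interpolated), and the
trapezoidal area under its positive part.

Refinement produces a *broad* decrease reaching *high* CI values, so a
refined culture has a wide difference peak located at large `tau`; a
weakly-correlated culture that decorrelates mildly has a narrow peak at
small `tau`. The classification rule is therefore
`width >= width_min AND location >= location_min`. No published numeric
rule exists (refinement was originally verified visually), so the default
thresholds are calibrated on this package's synthetic benchmark: across
15 refining and 15 non-refining default-scenario cultures the two metric
clusters are disjoint, and the defaults (`width_min = 0.125`,
`location_min = 0.12`) sit at the gap midpoints. They are configuration,
not constants. The AUC metric is computed and reported but deliberately
not used in the rule: it is known to be the weaker separator of the
two-cluster structure.

## The synthetic-culture generator

The generator is the study-conditions oracle, so its defaults are fixed
once and the tests run against them:

* **Field and recording**: 0.64 mm² (1007 × 1007 px at 0.8 µm/px), 200
  neurons by default, three 60 s epochs (baseline / during / after) at
  5 Hz.
* **Spiking**: network-burst onsets are homogeneous Poisson, shared by all
  neurons; a neuron joins a burst with its participation probability,
  emitting one spike jittered by N(0, 30 ms); independent Poisson
  background spikes are superimposed. Participation is the correlation
  dial (expected STTC increases monotonically with it). A refining culture
  runs 0.55 participation at baseline, then 0.85 for the Arc-positive
  subset and 0.25 for the rest; a non-refining culture is an initially
  weakly correlated network (0.35) declining mildly and uniformly to 0.25.
  Burst and background rates rise after stimulation (0.35→0.50 Hz and
  0.10→0.18 Hz), so expected firing rates increase while correlations
  fall — the phenomenon's defining dissociation. (The rate rise holds in
  expectation; the Poisson variability of a single epoch's burst count,
  SD ≈ √21 bursts, can mask it in an individual culture.)
* **Markers**: intensities are two normals separated by 5 negative-SDs
  (N(100, 20) vs N(200, 20)). 90% of cells are NeuN-positive; 10% of
  cells are Arc-positive (the refined set, exactly, in refining cultures);
  82.7% of Arc-positive cells are also c-Fos-positive and a further 6.2%
  of cells are c-Fos-only, so 16.2% of cells express at least one IEG.
  Arc-positive nuclei are drawn within a 150 px (120 µm) cluster radius.
* **Fluorescence**: AR(1) calcium with per-spike jumps, shared exponential
  photobleach, additive Gaussian noise (default SNR 10); one master seed
  drives counter-based substreams per neuron and stage, so cultures are
  bit-reproducible.

What the generator does **not** emulate — and therefore what passing tests
cannot certify on real data: touching/overlapping nuclei and segmentation
errors, excitatory/inhibitory cell-type structure, nonlinear or saturating
indicator dynamics, slow network-state drift within an epoch, non-Gaussian
noise, and any biological coupling between Arc expression and activity
beyond the constructed labels. The burst statistics themselves are free
parameters chosen to be plausible for dissociated cultures, not fits to
recordings.

## Cohort regression

`stepwise_linear_model()` performs forward/backward selection by partial-F
p-values (enter below 0.05, remove above 0.10 — the documented defaults of
the standard stepwise tools), reporting per-term estimates, SEs, t and p,
the regression/error/total sum-of-squares partition and adjusted R².
Exactly collinear candidates can never co-enter: a term adding no sum of
squares has partial F = 0. The packaged benchmark
(`simulate_regression_cohort()`) generates 17-culture cohorts in which the
Arc-positive proportion follows
`1 - 0.269 × final CI + 0.250 × refinement + N(0, 0.05)` with
firing-rate and initial-CI predictors carrying no signal; selection should
recover exactly the two generating terms with coefficients within sampling
error. (The source analysis this benchmark mirrors prints the final-CI
coefficient inconsistently across its own model line and estimate table;
the benchmark uses the model-line value, −0.269, and makes no attempt to
adjudicate.)

## Numerical choices and degenerate inputs

* STTC denominators within 1e-12 of zero, or empty trains, yield missing
  values, never zeros.
* Spike-distance comparisons use `<= Delta-t + 1e-12` so that boundary
  coincidences are inclusive and robust to float noise.
* The EM enforces an SD floor of 1e-6 × the sample SD; a dying component
  stops iteration and returns the best iterate.
* The stretched-exponential fit requires ≥ 5 interior points; all-zero or
  all-one curves are a degenerate-fit error; Levenberg-Marquardt failure
  falls back to a Nelder-Mead iterate flagged `converged = FALSE`.
* An all-nonpositive ICD difference curve yields zero metrics with a
  warning, and classifies as not refined.
* Empty label groups yield missing means with warnings; a culture with no
  Arc-positive cells completes the pipeline with Arc summaries missing.

## Problem sizes

The shipped tests and analysis scripts use scaled-down instances chosen so
that every property is exercised at meaningful power: 60-neuron cultures
for the 50-culture refinement benchmark, 120-neuron cultures in the
analysis scripts, 40 cells on the deconvolution route, 100 random train
pairs for the STTC oracle comparison, and 100 replicate cohorts for the
regression benchmark. These sizes are the package's own choices; all
functions accept the full-scale defaults.

## Known limitations

Correlated firing is not synaptic connectivity; the pipeline quantifies
functional coupling only. The deconvolution is a MAP point estimate with
no uncertainty; the ICD fit summarizes the strength distribution but its
parameters carry no inferential error bars; and the refinement thresholds,
while calibrated and overridable, remain a binary rule imposed on a
continuous phenomenon.
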