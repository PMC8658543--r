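# arcnet

Linking immediate-early-gene expression to functional network refinement in
cultured neurons.

Dissociated hippocampal cultures driven into chemical long-term potentiation
(4-aminopyridine + bicuculline + forskolin) show a characteristic
restructuring of their activity: firing rates rise, average pairwise
correlation falls, and a small subset of neurons — enriched for the
immediate-early-gene markers Arc and c-Fos — *increases* its mutual
correlation. `arcnet` implements the complete analysis chain needed to
quantify this **refinement** from raw inputs, for experimentalists and
computational neuroscientists working with widefield calcium imaging of
cultures:

* **Segmentation & labeling** — DAPI-based nuclear ROIs (Otsu + connected
  components + area filter), per-ROI marker intensities, two-normal mixture
  fitting by EM, and the 3-SD positivity rule
  (threshold = `mu_neg + 3 * sigma_neg`, i.e. above 99.7% of the negative
  population), yielding NeuN/Arc/c-Fos labels and the four Arc×c-Fos groups.
* **Trace processing** — per-ROI fluorescence extraction, background and
  photobleach correction from the silent lowest-decile cells, dF/F,
  network-peak detection, and fast-oopsi-style MAP spike deconvolution
  (AR(1) calcium, Gaussian noise, sparse nonnegative spike prior).
* **STTC networks** — the spike time tiling coefficient with Δt = 50 ms,

  ```
  STTC = 1/2 * ( (P_A − T_B)/(1 − P_A·T_B) + (P_B − T_A)/(1 − P_B·T_A) )
  ```

  as the pairwise correlation index (CI), assembled into per-epoch adjacency
  matrices; total flow (node strength), group-wise CI means,
  positive/negative correlation-change classification, Arc-pair fraction
  curves, and centroid distance analyses (0.8 µm/px).
* **ICD refinement metrics** — survival curves of normalized node strength
  fitted by the stretched exponential `d(τ) = exp(−α τ^β)`; baseline-minus-
  after difference curves summarized by peak width, height, location and
  AUC; refinement called when the peak is both wide and at large τ.
* **Cohort regression** — stepwise linear modeling (partial-F selection,
  p_enter 0.05 / p_remove 0.10) of Arc-positive percentage against firing
  rates, CI and refinement status.
* **Synthetic cultures** — a ground-truthed generator (network-burst spike
  trains with a participation dial, AR(1) fluorescence, renderable
  nuclear/marker images, bimodal intensities, 82.7% Arc⊂c-Fos overlap,
  spatially clustered Arc nuclei) so the whole pipeline is testable without
  experimental data.

See `vignettes/network-refinement.Rmd` for the models, parameter defaults
and design decisions.

## Worked example

```r
library(arcnet)

# a 120-neuron culture that undergoes refinement after stimulation
cu  <- generate_three_epoch_dataset(refinement = TRUE, seed = 20260921, n_neurons = 120)
res <- run_pipeline(cu)

res$mean_ci
#> baseline   during    after
#>    0.289    0.229    0.100

res$group_ci$after$neun_arc
#>        set    mean_ci n_pairs
#>    Arc-Arc 0.39245817      66
#>   Arc-NeuN 0.18113408    1152
#>  NeuN-NeuN 0.07588271    4560

res$icd_metrics
#> <icd_metrics: peak 0.961 at tau 0.18, width 0.196, auc 0.186, refined=TRUE>
```

The network's mean CI falls by 65% after stimulation while the Arc-Arc
pairs end up four times more correlated than the network average — the
refinement signature. The ICD difference peak is wide (0.196) and located
at large τ (0.18), so the culture is classified refined; a non-refining
culture run the same way yields `width 0.092, location 0.12,
refined=FALSE`. The same seed reproduces every number bit for bit.

The `analysis/` directory holds the numbered drivers that run these stages
over both study conditions and write their tables under `results/`:
`01_simulate.R`, `02_segment_label.R`, `03_traces_spikes.R`,
`04_network_icd.R`, `05_cohort_regression.R`.

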