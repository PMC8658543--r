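#!/usr/bin/env Rscript
# Generate the ground-truthed synthetic cultures used by the downstream
# analysis scripts: one culture that undergoes refinement after chemical LTP
# induction and one that does not. Writes spike tables, centroids, truth
# labels and marker intensities as CSV under results/cultures/.
#
# 120 neurons per culture keeps the full downstream STTC/ICD analysis fast
# while staying in the 10^2-10^3 cells-per-field range of a 0.64 mm^2 field.

suppressPackageStartupMessages(library(arcnet))
seed <- 20260921L
n_neurons <- 120L
out <- "results/cultures"

for (cond in c(refined = TRUE, unrefined = FALSE)) {
  cu <- generate_three_epoch_dataset(refinement = cond, seed = seed,
                                     n_neurons = n_neurons)
  dir <- file.path(out, if (cond) "refined" else "unrefined")
  write_culture_csv(cu, dir)
  lab <- cu$true_labels
  cat(sprintf(
    "%s culture: %d neurons, %d NeuN+, %d Arc+ (%.1f%% of cells), %d c-Fos+\n",
    if (cond) "refined" else "unrefined", n_neurons, sum(lab$neun),
    sum(lab$arc), 100 * mean(lab$arc), sum(lab$cfos)))
  cat(sprintf("  Arc+ cells also c-Fos+: %.1f%% (generative default 82.7%%)\n",
              100 * mean(lab$cfos[lab$arc])))
  cat(sprintf("  mean firing rate baseline/after: %.3f / %.3f Hz\n",
      mean(vapply(cu$spike_trains$baseline, firing_rate, numeric(1))),
      mean(vapply(cu$spike_trains$after, firing_rate, numeric(1)))))
}
cat("cultures written under", out, "\n")
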