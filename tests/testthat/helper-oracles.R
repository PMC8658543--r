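# Independent oracles for the STTC terms, kept free of the package's
# interval-union code path.
#
# Spike times for oracle comparisons are drawn on a 1 ms lattice. All tile
# boundaries (delta_t = 50 ms is a lattice multiple) then fall on lattice
# points, so the tiled-time measure evaluated at 1 ms cell midpoints is
# *exact*, and agreement can be required at 1e-6.

# random lattice spike train: times are multiples of 1 ms
lattice_train <- function(n_spikes, duration_s = 60) {
  t <- sort(sample.int(duration_s * 1000 - 1, n_spikes)) / 1000
  spike_train(t, duration_s)
}

# fine-grid measure of the tiled time fraction via per-cell min distance
oracle_ttf <- function(train, delta_t_s = 0.05, cell_s = 0.001) {
  times <- train$times_s
  if (!length(times)) return(0)
  n_cells <- round(train$duration_s / cell_s)
  mids <- (seq_len(n_cells) - 0.5) * cell_s
  dmin <- rep(Inf, n_cells)
  for (t in times) dmin <- pmin(dmin, abs(mids - t))
  mean(dmin <= delta_t_s)
}

# brute-force O(nA * nB) tiled spike proportion
oracle_tsp <- function(a, b, delta_t_s = 0.05) {
  ta <- a$times_s; tb <- b$times_s
  if (!length(ta)) return(NA_real_)
  if (!length(tb)) return(0)
  hit <- vapply(ta, function(t) min(abs(t - tb)) <= delta_t_s, logical(1))
  mean(hit)
}

oracle_sttc <- function(a, b, delta_t_s = 0.05) {
  if (!length(a$times_s) || !length(b$times_s)) return(NA_real_)
  ta <- oracle_ttf(a, delta_t_s); tb <- oracle_ttf(b, delta_t_s)
  pa <- oracle_tsp(a, b, delta_t_s); pb <- oracle_tsp(b, a, delta_t_s)
  0.5 * ((pa - tb) / (1 - pa * tb) + (pb - ta) / (1 - pb * ta))
}

# greedy matching F1 between inferred and true spike frames (+/- 1 frame)
spike_f1 <- function(inferred_times, true_times, frame_rate_hz = 5,
                     tol_frames = 1) {
  tf <- sort(unique(pmin(pmax(ceiling(true_times * frame_rate_hz), 1),
                         .Machine$integer.max)))
  inf <- round(inferred_times * frame_rate_hz + 0.5)
  used <- rep(FALSE, length(inf))
  tp <- 0L
  for (t in tf) {
    j <- which(!used & abs(inf - t) <= tol_frames)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  prec <- if (length(inf)) tp / length(inf) else 0
  rec <- if (length(tf)) tp / length(tf) else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# compact refined/non-refined metric extraction used by the ICD benchmarks
culture_icd_metrics <- function(refinement, seed, n_neurons = 60) {
  cu <- generate_three_epoch_dataset(refinement = refinement, seed = seed,
                                     n_neurons = n_neurons)
  mb <- adjacency_matrix(cu$spike_trains$baseline)
  ma <- adjacency_matrix(cu$spike_trains$after)
  d <- icd_difference(strength_survival_curve(mb),
                      strength_survival_curve(ma))
  difference_metrics(d)
}
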