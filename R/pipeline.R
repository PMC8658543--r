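#' Run the full per-culture analysis pipeline
#'
#' Orchestrates all stages for one culture: simulate (or ingest) the
#' three-epoch recording, threshold marker intensities with the two-normal
#' mixture and label cells, obtain per-neuron spike trains (ground-truth
#' trains by default, or regenerated through the AR(1) fluorescence forward
#' model and MAP deconvolution when `use_deconvolution = TRUE`), then compute
#' firing rates, STTC adjacency matrices, group CI means, ICD refinement
#' metrics, correlation-change classification and distance summaries. Only
#' NeuN-positive cells enter the neuron-level analyses.
#'
#' @param culture a `synthetic_culture` from [generate_three_epoch_dataset()]
#'   or an equivalent ingested structure (see [read_culture_csv()]).
#' @param delta_t_s STTC tiling half-window (seconds).
#' @param refinement_thresholds list with `width_min`, `location_min`.
#' @param use_deconvolution route spikes through fluorescence synthesis and
#'   [infer_spikes()] instead of using the trains directly.
#' @param dff_mode dF/F mode passed to [correct_and_normalize()] on the
#'   deconvolution route.
#' @param pixel_size_um physical pixel size for the distance analysis.
#' @param seed seed for the (deterministic) deconvolution-route noise.
#' @return object of class `culture_result`; see [write_result_bundle()] for
#'   the serialized layout.
#' @export
run_pipeline <- function(culture,
                         delta_t_s = 0.05,
                         refinement_thresholds = default_refinement_thresholds(),
                         use_deconvolution = FALSE,
                         dff_mode = "dff",
                         pixel_size_um = 0.8,
                         seed = 1L) {
  epochs <- names(culture$spike_trains)
  n <- nrow(culture$marker_intensities)

  # --- labeling: per-channel mixture fits and 3-SD thresholds --------------
  mi <- culture$marker_intensities
  fits <- lapply(stats::setNames(c("neun", "arc", "cfos"),
                                 c("neun", "arc", "cfos")),
                 function(ch) fit_two_normal_mixture(mi[[ch]]))
  thresholds <- lapply(fits, function(f) {
    # a collapsed fit (components within 1 SD) means the channel has no
    # separable positive population: every cell is scored negative
    if (f$mu_pos - f$mu_neg < max(f$sigma_neg, f$sigma_pos)) Inf
    else positivity_threshold(f)
  })
  labels <- assign_labels(mi, thresholds)

  # --- spike trains per epoch ----------------------------------------------
  trains <- culture$spike_trains
  if (use_deconvolution) {
    trains <- lapply(stats::setNames(epochs, epochs), function(ep) {
      raw <- spikes_to_fluorescence(
        culture$spike_trains[[ep]],
        frame_rate_hz = culture$params$frame_rate_hz %||% 5,
        bleach_rate = 5e-4,
        seed = substream_seed(seed, 801L, match(ep, epochs)))
      corr <- correct_and_normalize(raw, mode = dff_mode)
      dur <- culture$spike_trains[[ep]][[1]]$duration_s
      lapply(seq_len(nrow(corr)), function(i)
        infer_spikes(corr[i, ], frame_rate_hz = attr(corr, "frame_rate_hz")))
    })
  }

  neuronal <- which(labels$neun_pos)
  if (length(neuronal) < 2)
    stop("pipeline needs at least 2 NeuN-positive cells", call. = FALSE)
  lab_n <- labels[neuronal, , drop = FALSE]
  cent_n <- as.matrix(culture$roi_centroids)[neuronal, , drop = FALSE]

  # --- firing rates ---------------------------------------------------------
  rates <- vapply(epochs, function(ep)
    vapply(trains[[ep]][neuronal], firing_rate, numeric(1)),
    numeric(length(neuronal)))
  rate_changes <- lapply(stats::setNames(setdiff(epochs, "baseline"),
                                         setdiff(epochs, "baseline")),
                         function(ep)
                           normalized_rate_change(rates[, "baseline"],
                                                  rates[, ep]))

  # --- STTC adjacency per epoch ---------------------------------------------
  adj <- lapply(stats::setNames(epochs, epochs), function(ep)
    adjacency_matrix(trains[[ep]][neuronal], delta_t_s, epoch = ep))
  mean_ci <- vapply(adj, function(m) mean(m[upper.tri(m)], na.rm = TRUE),
                    numeric(1))
  group_ci <- lapply(adj, function(m) list(
    neun_arc = group_mean_ci(m, lab_n, "neun_arc"),
    arc_cfos = suppressWarnings(group_mean_ci(m, lab_n, "arc_cfos"))))

  # --- ICD refinement --------------------------------------------------------
  sc_base <- strength_survival_curve(adj$baseline, epoch = "baseline")
  sc_after <- strength_survival_curve(adj$after, epoch = "after")
  diff_curve <- icd_difference(sc_base, sc_after)
  metrics <- classify_refinement(difference_metrics(diff_curve),
                                 width_min = refinement_thresholds$width_min,
                                 location_min = refinement_thresholds$location_min)

  # --- correlation changes and distances ------------------------------------
  changes <- classify_correlation_changes(adj$baseline, adj$after,
                                          labels = lab_n,
                                          centroids = cent_n,
                                          pixel_size_um = pixel_size_um)
  arc_curve <- if (any(lab_n$arc_pos) && nrow(changes))
    arc_pair_fraction_vs_threshold(changes) else NULL
  dist_um <- pair_distances(cent_n, pixel_size_um)
  dist_curve <- mean_distance_above_threshold(adj$after, dist_um)

  pct <- function(x) 100 * mean(x)
  structure(list(
    n_rois = n, n_neuronal = length(neuronal),
    mixture_fits = fits, thresholds = thresholds, labels = labels,
    rates = rates, rate_changes = rate_changes,
    mean_rate_change = vapply(rate_changes, mean, numeric(1), na.rm = TRUE),
    adjacency = adj, mean_ci = mean_ci,
    ci_change = (mean_ci - mean_ci["baseline"]) / mean_ci["baseline"],
    group_ci = group_ci,
    survival_curves = list(baseline = sc_base, after = sc_after),
    icd_difference = diff_curve, icd_metrics = metrics,
    refined = metrics$refined,
    arc_pct = pct(lab_n$arc_pos), cfos_pct = pct(lab_n$cfos_pos),
    arc_cfos_overlap_pct = if (any(lab_n$arc_pos))
      pct(lab_n$cfos_pos[lab_n$arc_pos]) else NA_real_,
    changes = changes, arc_fraction_curve = arc_curve,
    distance_curve = dist_curve,
    params = list(delta_t_s = delta_t_s,
                  refinement_thresholds = refinement_thresholds,
                  use_deconvolution = use_deconvolution, seed = seed)
  ), class = "culture_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.culture_result <- function(x, ...) {
  cat(sprintf(
    paste0("<culture_result: %d/%d NeuN+ cells, Arc+ %.1f%%, refined=%s>\n",
           "  mean CI: %s\n"),
    x$n_neuronal, x$n_rois, x$arc_pct, x$refined,
    paste(sprintf("%s %.3f", names(x$mean_ci), x$mean_ci), collapse = ", ")))
  invisible(x)
}

#' Simulate a cohort table for the Arc-percentage regression benchmark
#'
#' Generates per-culture predictors (firing rates initial/final/change, CI
#' initial/final/change, refinement status) and an Arc-positive-percentage
#' response following the published model line
#' `arc_pct = 1 - 0.269 * final CI + 0.250 * refinement + noise`,
#' on the 0-1 proportion scale.
#'
#' @param n_cultures cohort size (default 17, the cohort size the model was
#'   reported for).
#' @param seed integer seed.
#' @param beta0,beta_ci,beta_ref generating coefficients.
#' @param noise_sd residual SD (default 0.05).
#' @return data frame with `arc_pct` and the seven candidate predictors.
#' @export
simulate_regression_cohort <- function(n_cultures = 17, seed = 1L,
                                       beta0 = 1, beta_ci = -0.269,
                                       beta_ref = 0.250, noise_sd = 0.05) {
  with_seed(substream_seed(seed, 901L), {
    ci_initial <- stats::runif(n_cultures, 0, 1)
    ci_final <- stats::runif(n_cultures, 0.05, 0.95)
    rate_initial <- stats::runif(n_cultures, 0.1, 0.6)
    rate_final <- rate_initial * stats::runif(n_cultures, 0.8, 1.6)
    refinement <- rep_len(c(0, 1), n_cultures)[sample.int(n_cultures)]
    arc_pct <- beta0 + beta_ci * ci_final + beta_ref * refinement +
      stats::rnorm(n_cultures, 0, noise_sd)
    data.frame(arc_pct = arc_pct,
               rate_initial = rate_initial, rate_final = rate_final,
               rate_change = rate_final - rate_initial,
               ci_initial = ci_initial, ci_final = ci_final,
               ci_change = ci_final - ci_initial,
               refinement = refinement)
  })
}
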