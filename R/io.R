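#' Write a culture's inputs as plain-text files
#'
#' Serializes spike times (`spikes.csv`: `neuron_id`, `epoch`, `time_s`),
#' centroids and ground-truth labels (`centroids.csv`, `truth_labels.csv`),
#' marker intensities (`intensities.csv`) and the scenario parameters
#' (`scenario.json`).
#'
#' @param culture a `synthetic_culture`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_culture_csv <- function(culture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spikes <- do.call(rbind, lapply(names(culture$spike_trains), function(ep) {
    tr <- culture$spike_trains[[ep]]
    do.call(rbind, lapply(seq_along(tr), function(i) {
      if (!length(tr[[i]]$times_s)) return(NULL)
      data.frame(neuron_id = i, epoch = ep, time_s = tr[[i]]$times_s)
    }))
  }))
  utils::write.csv(spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(culture$roi_centroids, file.path(dir, "centroids.csv"),
                   row.names = FALSE)
  utils::write.csv(culture$true_labels, file.path(dir, "truth_labels.csv"),
                   row.names = FALSE)
  utils::write.csv(culture$marker_intensities,
                   file.path(dir, "intensities.csv"), row.names = FALSE)
  keep <- Filter(function(x) !is.function(x), culture$params)
  jsonlite::write_json(
    c(keep, list(epochs = names(culture$spike_trains),
                 n_neurons = nrow(culture$true_labels))),
    file.path(dir, "scenario.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a culture back from its plain-text files
#'
#' Inverse of [write_culture_csv()]; the result can be passed to
#' [run_pipeline()].
#'
#' @param dir directory written by [write_culture_csv()].
#' @return a `synthetic_culture`-shaped list.
#' @export
read_culture_csv <- function(dir) {
  scen <- jsonlite::read_json(file.path(dir, "scenario.json"),
                              simplifyVector = TRUE)
  spikes <- utils::read.csv(file.path(dir, "spikes.csv"))
  n <- scen$n_neurons
  trains <- lapply(stats::setNames(scen$epochs, scen$epochs), function(ep) {
    sub <- spikes[spikes$epoch == ep, , drop = FALSE]
    lapply(seq_len(n), function(i)
      spike_train(sub$time_s[sub$neuron_id == i], scen$duration_s))
  })
  structure(list(
    spike_trains = trains,
    roi_centroids = utils::read.csv(file.path(dir, "centroids.csv")),
    true_labels = utils::read.csv(file.path(dir, "truth_labels.csv")),
    marker_intensities = utils::read.csv(file.path(dir, "intensities.csv")),
    refinement_truth = isTRUE(scen$refinement),
    params = scen), class = "synthetic_culture")
}

#' Write a pipeline result bundle to disk
#'
#' Emits `summary.json` (versioned schema), one `adjacency_<epoch>.csv` per
#' epoch, `rates.csv`, `labels.csv`, `icd_metrics.json`, `changes.csv`,
#' `distances.csv`, `group_ci.csv` and `survival_curves.csv`.
#'
#' @param result a `culture_result` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  epochs <- names(result$adjacency)
  for (ep in epochs)
    utils::write.csv(result$adjacency[[ep]],
                     file.path(dir, paste0("adjacency_", ep, ".csv")),
                     row.names = FALSE)
  rates <- as.data.frame(result$rates)
  names(rates) <- paste0("rate_", epochs)
  for (ep in names(result$rate_changes))
    rates[[paste0("rate_change_", ep)]] <- result$rate_changes[[ep]]
  utils::write.csv(cbind(neuron = seq_len(nrow(rates)), rates),
                   file.path(dir, "rates.csv"), row.names = FALSE)
  utils::write.csv(result$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  utils::write.csv(result$changes, file.path(dir, "changes.csv"),
                   row.names = FALSE)
  utils::write.csv(result$distance_curve, file.path(dir, "distances.csv"),
                   row.names = FALSE)
  gc_tab <- do.call(rbind, lapply(epochs, function(ep) {
    t1 <- result$group_ci[[ep]]$neun_arc
    t2 <- result$group_ci[[ep]]$arc_cfos
    cbind(epoch = ep, grouping = rep(c("neun_arc", "arc_cfos"),
                                     c(nrow(t1), nrow(t2))),
          rbind(t1, t2))
  }))
  utils::write.csv(gc_tab, file.path(dir, "group_ci.csv"), row.names = FALSE)
  sc_tab <- do.call(rbind, lapply(names(result$survival_curves), function(ep)
    cbind(epoch = ep, as.data.frame(result$survival_curves[[ep]]))))
  utils::write.csv(sc_tab, file.path(dir, "survival_curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(result$icd_metrics),
                       file.path(dir, "icd_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  summary <- result_summary(result)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Machine-readable summary of a culture result
#'
#' @param result a `culture_result`.
#' @return a named list matching the shipped summary schema
#'   (`inst/extdata/summary_schema.json`).
#' @export
result_summary <- function(result) {
  list(
    schema_version = "1.0",
    n_rois = result$n_rois, n_neuronal = result$n_neuronal,
    mean_ci = as.list(result$mean_ci),
    ci_change = as.list(result$ci_change),
    mean_rate_change = as.list(result$mean_rate_change),
    arc_pct = result$arc_pct, cfos_pct = result$cfos_pct,
    arc_cfos_overlap_pct = result$arc_cfos_overlap_pct,
    icd_metrics = unclass(result$icd_metrics),
    refined = result$refined,
    thresholds = result$thresholds,
    params = result$params
  )
}

#' Validate a summary list against the shipped schema
#'
#' Lightweight structural validation: every field required by the schema
#' must be present and of the declared JSON type.
#'
#' @param summary named list as produced by [result_summary()] (or read back
#'   from `summary.json`).
#' @return `TRUE` (invisibly) or an error describing the first violation.
#' @export
validate_result_summary <- function(summary) {
  schema <- jsonlite::read_json(
    system.file("extdata", "summary_schema.json", package = "arcnet"),
    simplifyVector = TRUE)
  for (field in names(schema$required_fields)) {
    if (!field %in% names(summary))
      stop("summary is missing required field: ", field, call. = FALSE)
    type <- schema$required_fields[[field]]
    val <- summary[[field]]
    ok <- switch(type,
                 number = is.numeric(val) ||
                   (is.list(val) && all(vapply(val, is.numeric, logical(1)))),
                 string = is.character(val),
                 boolean = is.logical(val),
                 object = is.list(val),
                 TRUE)
    if (!ok) stop(sprintf("summary field '%s' is not of type '%s'",
                          field, type), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write an image or stack as TIFF
#'
#' Float TIFF writer for rendered nuclear/marker images and calcium movies
#' (one page per frame).
#'
#' @param x matrix, or array `h x w x frames`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(x, path) {
  if (length(dim(x)) == 3L) {
    pages <- lapply(seq_len(dim(x)[3]), function(t) x[, , t])
  } else pages <- list(as.matrix(x))
  mx <- max(vapply(pages, max, numeric(1)), 1)
  pages <- lapply(pages, function(p) p / mx)  # tiff expects [0, 1]
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}
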