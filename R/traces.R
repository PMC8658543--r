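#' Extract per-ROI fluorescence traces from a movie
#'
#' All pixels within each ROI are averaged per frame to give a single time
#' course per cell.
#'
#' @param movie numeric array `height x width x frames`.
#' @param rois a [roi_set()] whose label image matches the movie geometry.
#' @param frame_rate_hz imaging rate stored on the result.
#' @return a raw [fluorescence_matrix()] (cells x frames, in `roi_id` order).
#' @export
extract_traces <- function(movie, rois, frame_rate_hz = 5) {
  stopifnot(inherits(rois, "roi_set"), length(dim(movie)) == 3L)
  if (!all(dim(movie)[1:2] == dim(rois$label_image)))
    stop("movie frame geometry does not match the ROI label image",
         call. = FALSE)
  lab <- rois$label_image
  idx <- which(lab > 0L)
  cell <- factor(lab[idx], levels = rois$roi_id)
  n_frames <- dim(movie)[3]
  out <- matrix(0, length(rois$roi_id), n_frames)
  for (t in seq_len(n_frames)) {
    fr <- movie[, , t]
    out[, t] <- tapply(fr[idx], cell, mean)
  }
  fluorescence_matrix(out, frame_rate_hz, kind = "raw")
}

#' Background/photobleach correction and dF/F normalization
#'
#' The cells that were silent during the recording — the lowest tenth
#' percentile of the population, ranked by temporal variance of the raw
#' trace — define a per-frame background `b(t)` (their mean raw value at
#' each time point). Subtracting `b(t)` removes background and corrects the
#' photobleaching component shared across cells. By default the subtracted
#' trace is then baseline-normalized to a conventional dF/F,
#' `(F - b(t) - F0) / F0`, with `F0` the per-cell 10th percentile of the
#' background-subtracted trace; `mode = "subtract_only"` stops at the
#' subtraction (the literal reading of the correction as published). Cells
#' whose `F0` is not positive (e.g. the silent reference cells themselves)
#' are left unscaled.
#'
#' @param raw a raw [fluorescence_matrix()] with at least 10 cells.
#' @param mode `"dff"` (default) or `"subtract_only"`.
#' @param silent_fraction fraction of cells defining the background
#'   (default 0.1).
#' @return a corrected [fluorescence_matrix()] (`kind = "corrected"`) with
#'   attributes `silent_cells` (indices used for the background) and
#'   `unscaled_cells` (cells left unnormalized).
#' @export
correct_and_normalize <- function(raw, mode = c("dff", "subtract_only"),
                                  silent_fraction = 0.1) {
  mode <- match.arg(mode)
  stopifnot(inherits(raw, "fluorescence_matrix"))
  n <- nrow(raw)
  if (n < 10L) stop("background correction needs at least 10 cells",
                    call. = FALSE)
  v <- apply(raw, 1, stats::var)
  n_bg <- max(1L, floor(silent_fraction * n))
  silent <- order(v)[seq_len(n_bg)]
  bg <- colMeans(raw[silent, , drop = FALSE])
  sub <- sweep(unclass(raw), 2, bg, `-`)
  unscaled <- integer(0)
  if (mode == "dff") {
    f0 <- apply(sub, 1, stats::quantile, probs = 0.1, names = FALSE)
    pos <- f0 > .Machine$double.eps^0.5
    unscaled <- which(!pos)
    sub[pos, ] <- (sub[pos, , drop = FALSE] - f0[pos]) / f0[pos]
  }
  out <- fluorescence_matrix(sub, attr(raw, "frame_rate_hz"),
                             kind = "corrected", epoch = attr(raw, "epoch"))
  attr(out, "silent_cells") <- silent
  attr(out, "unscaled_cells") <- unscaled
  out
}

#' Detect network-level fluorescence peaks
#'
#' Local maxima of a 1-D trace (typically the total network fluorescence)
#' filtered by topographic prominence and a minimum peak separation; when
#' peaks compete within the separation window the higher one wins.
#'
#' @param trace numeric vector.
#' @param min_prominence minimum prominence; default 2 robust SDs
#'   (`mad`) of the trace.
#' @param min_separation_frames minimum index distance between kept peaks.
#' @return integer vector of peak frame indices (ascending).
#' @export
detect_network_peaks <- function(trace, min_prominence = NULL,
                                 min_separation_frames = 5L) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (n < 3L) return(integer(0))
  if (is.null(min_prominence)) min_prominence <- 2 * stats::mad(trace)
  d <- diff(trace)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    left <- seq_len(p - 1L)
    higher_l <- left[trace[left] > trace[p]]
    base_l <- if (length(higher_l)) min(trace[(max(higher_l)):p]) else min(trace[1:p])
    right <- seq.int(p + 1L, n)
    higher_r <- right[trace[right] > trace[p]]
    base_r <- if (length(higher_r)) min(trace[p:(min(higher_r))]) else min(trace[p:n])
    trace[p] - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (length(keep) <= 1L) return(keep)
  # enforce separation, higher peaks first
  keep <- keep[order(trace[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (p in keep) {
    if (!length(sel) || all(abs(sel - p) >= min_separation_frames))
      sel <- c(sel, p)
  }
  sort(sel)
}

#' Firing rate of a spike train
#'
#' Number of spikes divided by the total recording time.
#'
#' @param train a [spike_train()].
#' @return rate in Hz.
#' @export
firing_rate <- function(train) {
  stopifnot(is_spike_train(train))
  length(train$times_s) / train$duration_s
}

#' Normalized firing-rate change relative to baseline
#'
#' `(rate_epoch - rate_baseline) / rate_baseline` per neuron; neurons silent
#' at baseline are excluded (`NA`, with a message) from the per-network
#' average, which is the mean of the per-neuron normalized changes.
#'
#' @param rate_baseline,rate_epoch numeric vectors of per-neuron rates (Hz).
#' @return numeric vector of normalized changes (`NA` where baseline is 0).
#' @export
normalized_rate_change <- function(rate_baseline, rate_epoch) {
  stopifnot(length(rate_baseline) == length(rate_epoch))
  zero <- rate_baseline <= 0
  if (any(zero))
    message(sum(zero), " neuron(s) silent at baseline excluded from ",
            "normalized rate change")
  ifelse(zero, NA_real_, (rate_epoch - rate_baseline) / rate_baseline)
}
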