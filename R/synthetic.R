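#' Generate network-burst spike trains
#'
#' Minimal generative model for the synchronized bursting of dissociated
#' cultures: network-burst onsets follow a homogeneous Poisson process shared
#' by all neurons; each neuron joins a given burst with its participation
#' probability and, when it does, emits one spike jittered around the onset;
#' independent Poisson background spikes are superimposed. Participation is
#' the correlation dial — expected pairwise STTC grows with it.
#'
#' @param n_neurons number of neurons (> 0).
#' @param duration_s recording length in seconds (> 0).
#' @param burst_rate_hz network-burst onset rate (>= 0).
#' @param participation scalar or per-neuron vector of burst-participation
#'   probabilities in `[0, 1]`.
#' @param jitter_sd_s SD of the within-burst spike-time jitter (seconds).
#' @param background_rate_hz independent Poisson rate per neuron (>= 0).
#' @param seed integer master seed; every neuron draws from its own derived
#'   substream, so results are bit-reproducible.
#' @return list of `n_neurons` [spike_train()] objects.
#' @export
generate_burst_spike_trains <- function(n_neurons, duration_s,
                                        burst_rate_hz = 0.35,
                                        participation = 0.55,
                                        jitter_sd_s = 0.03,
                                        background_rate_hz = 0.1,
                                        seed = 1L) {
  if (n_neurons < 1 || duration_s <= 0)
    stop("invalid parameters: need n_neurons >= 1 and duration_s > 0",
         call. = FALSE)
  if (burst_rate_hz < 0 || background_rate_hz < 0 || jitter_sd_s < 0)
    stop("invalid parameters: rates and jitter must be >= 0", call. = FALSE)
  participation <- rep_len(participation, n_neurons)
  if (any(participation < 0 | participation > 1))
    stop("participation probabilities must lie in [0, 1]", call. = FALSE)

  onsets <- with_seed(substream_seed(seed, 101L), {
    k <- stats::rpois(1L, burst_rate_hz * duration_s)
    sort(stats::runif(k, 0, duration_s))
  })
  lapply(seq_len(n_neurons), function(i) {
    with_seed(substream_seed(seed, 202L, i), {
      joins <- stats::runif(length(onsets)) < participation[i]
      tb <- onsets[joins]
      if (jitter_sd_s > 0 && length(tb))
        tb <- tb + stats::rnorm(length(tb), 0, jitter_sd_s)
      nbg <- stats::rpois(1L, background_rate_hz * duration_s)
      t <- c(tb, stats::runif(nbg, 0, duration_s))
      spike_train(pmin(pmax(t, 0), duration_s), duration_s)
    })
  })
}

#' Default scenario parameters for a synthetic culture
#'
#' The conditions emulate a 0.64 mm^2 field recorded at 5 Hz for 60 s per
#' epoch (baseline, during and after chemical LTP induction), with burst
#' participation as the correlation dial. A refining culture starts strongly
#' correlated (all neurons join ~55% of network bursts); after stimulation
#' the designated refined (Arc-positive) subset rises to 85% participation
#' while the rest fall to 25%, yielding the refinement signature — a broad
#' global CI decrease with a selectively strengthened subset. A non-refining
#' culture (`participation_flat`) is an initially weakly correlated network
#' (participation 35%) whose correlations decline mildly and uniformly
#' (to 25%), so its ICD difference peak is narrow and sits at small tau.
#' Burst rate and background rate rise after stimulation so that mean firing
#' rate increases while mean correlation decreases. Marker intensities are two normals
#' separated by 5 negative-population SDs; 10% of neurons are Arc-positive,
#' 82.7% of those are also c-Fos-positive, and a further 6.2% of cells are
#' c-Fos-only (16.2% of cells express either IEG). Arc-positive nuclei
#' cluster spatially within a 150 px radius.
#'
#' @return named list of scenario parameters; override entries via
#'   [generate_three_epoch_dataset()]'s `...`.
#' @export
default_scenario <- function() {
  list(
    n_neurons = 200L,
    duration_s = 60,
    frame_rate_hz = 5,
    frame_px = 1007L,
    margin_px = 24,
    pixel_size_um = 0.8,
    neun_frac = 0.9,
    arc_frac = 0.10,
    arc_cfos_overlap = 0.827,
    cfos_only_frac = 0.062,
    cluster_radius_px = 150,
    burst_rate_hz = c(baseline = 0.35, during = 0.40, after = 0.50),
    background_rate_hz = c(baseline = 0.10, during = 0.12, after = 0.18),
    jitter_sd_s = 0.03,
    participation_refined = c(baseline = 0.55, during = 0.60, after = 0.85),
    participation_unrefined = c(baseline = 0.55, during = 0.45, after = 0.25),
    participation_flat = c(baseline = 0.35, during = 0.32, after = 0.25),
    intensity_mu_neg = 100, intensity_sd_neg = 20,
    intensity_mu_pos = 200, intensity_sd_pos = 20
  )
}

#' Generate a ground-truthed three-epoch synthetic culture
#'
#' Produces spike trains for the baseline / during / after epochs, ROI
#' centroids on the imaging field, ground-truth marker assignments
#' (NeuN/Arc/c-Fos), bimodal marker intensities, and the refinement truth
#' flag. With `refinement = TRUE` the Arc-positive truth set is exactly the
#' refined subset: its pairwise correlations rise after stimulation while the
#' network mean falls. With `refinement = FALSE` participation declines
#' uniformly and every group's correlation decreases.
#'
#' @param refinement logical; does this culture undergo refinement?
#' @param seed integer master seed.
#' @param ... overrides for entries of [default_scenario()].
#' @return object of class `synthetic_culture`: `spike_trains` (list of
#'   epochs, each a list of [spike_train()]), `roi_centroids` (data frame
#'   `x`, `y` in 0-based pixels), `true_labels` (data frame `neuron_id`,
#'   `neun`, `arc`, `cfos`, `refined`), `marker_intensities` (data frame
#'   `roi_id`, `neun`, `arc`, `cfos`), `refinement_truth`, `params`.
#' @export
generate_three_epoch_dataset <- function(refinement = TRUE, seed = 1L, ...) {
  p <- utils::modifyList(default_scenario(), list(...))
  n <- as.integer(p$n_neurons)
  if (n < 2) stop("need at least 2 neurons", call. = FALSE)
  if (p$arc_cfos_overlap < 0 || p$arc_cfos_overlap > 1)
    stop("arc_cfos_overlap must lie in [0, 1]", call. = FALSE)
  n_arc <- round(p$arc_frac * n)
  if (n_arc > n) stop("refined subset larger than the culture", call. = FALSE)

  # --- ground-truth labels -------------------------------------------------
  lab <- with_seed(substream_seed(seed, 301L), {
    neun <- rep(FALSE, n)
    neun[sample.int(n, round(p$neun_frac * n))] <- TRUE
    arc <- rep(FALSE, n)
    arc[sample(which(neun), min(n_arc, sum(neun)))] <- TRUE
    cfos <- rep(FALSE, n)
    cfos[arc] <- stats::runif(sum(arc)) < p$arc_cfos_overlap
    pool <- which(neun & !arc)
    n_cfos_only <- min(round(p$cfos_only_frac * n), length(pool))
    cfos[sample(pool, n_cfos_only)] <- TRUE
    data.frame(neuron_id = seq_len(n), neun = neun, arc = arc, cfos = cfos,
               refined = if (refinement) arc else rep(FALSE, n))
  })

  # --- spike trains: participation switches by group and epoch -------------
  epochs <- c("baseline", "during", "after")
  spike_trains <- lapply(stats::setNames(epochs, epochs), function(ep) {
    part <- if (refinement) {
      ifelse(lab$refined, p$participation_refined[[ep]],
             p$participation_unrefined[[ep]])
    } else rep(p$participation_flat[[ep]], n)
    part[!lab$neun] <- 0   # non-neuronal ROIs carry background events only
    generate_burst_spike_trains(
      n_neurons = n, duration_s = p$duration_s,
      burst_rate_hz = p$burst_rate_hz[[ep]], participation = part,
      jitter_sd_s = p$jitter_sd_s,
      background_rate_hz = p$background_rate_hz[[ep]],
      seed = substream_seed(seed, 401L, match(ep, epochs)))
  })

  # --- spatial layout: Arc-positive nuclei are clustered -------------------
  cent <- with_seed(substream_seed(seed, 501L), {
    lim <- c(p$margin_px, p$frame_px - 1 - p$margin_px)
    x <- stats::runif(n, lim[1], lim[2])
    y <- stats::runif(n, lim[1], lim[2])
    if (any(lab$arc)) {
      cxy <- stats::runif(2, lim[1] + p$cluster_radius_px,
                          lim[2] - p$cluster_radius_px)
      k <- sum(lab$arc)
      r <- p$cluster_radius_px * sqrt(stats::runif(k))
      th <- stats::runif(k, 0, 2 * pi)
      x[lab$arc] <- pmin(pmax(cxy[1] + r * cos(th), lim[1]), lim[2])
      y[lab$arc] <- pmin(pmax(cxy[2] + r * sin(th), lim[1]), lim[2])
    }
    data.frame(x = x, y = y)
  })

  # --- bimodal marker intensities ------------------------------------------
  intens <- with_seed(substream_seed(seed, 601L), {
    draw <- function(pos) {
      stats::rnorm(n, ifelse(pos, p$intensity_mu_pos, p$intensity_mu_neg),
                   ifelse(pos, p$intensity_sd_pos, p$intensity_sd_neg))
    }
    data.frame(roi_id = seq_len(n), neun = pmax(draw(lab$neun), 0),
               arc = pmax(draw(lab$arc), 0), cfos = pmax(draw(lab$cfos), 0))
  })

  structure(list(spike_trains = spike_trains, roi_centroids = cent,
                 true_labels = lab, marker_intensities = intens,
                 refinement_truth = refinement,
                 params = c(p, list(seed = seed, refinement = refinement))),
            class = "synthetic_culture")
}

#' @export
print.synthetic_culture <- function(x, ...) {
  cat(sprintf(
    "<synthetic_culture: %d neurons, %d epochs x %g s, refinement=%s, Arc+ n=%d>\n",
    nrow(x$true_labels), length(x$spike_trains), x$params$duration_s,
    x$refinement_truth, sum(x$true_labels$arc)))
  invisible(x)
}

#' Synthesize AR(1) calcium fluorescence from spike trains
#'
#' Forward model matching the assumptions of the MAP spike deconvolution:
#' per-frame calcium follows `C_t = gamma * C_{t-1} + n_t` (spikes binned per
#' frame), and fluorescence is
#' `F_t = amplitude * C_t * exp(-bleach_rate * t) + baseline + noise`.
#'
#' @param trains list of [spike_train()] sharing one duration.
#' @param gamma AR(1) decay per frame, in (0, 1). The default corresponds to
#'   a 1 s decay time imaged at 5 Hz (`exp(-0.2)`).
#' @param amplitude fluorescence jump per spike.
#' @param baseline additive offset.
#' @param noise_sd SD of additive Gaussian noise (default amplitude/10,
#'   i.e. SNR 10).
#' @param bleach_rate multiplicative exponential photobleach constant per
#'   frame (shared by all cells).
#' @param frame_rate_hz imaging rate (default 5 Hz).
#' @param seed integer seed for the noise.
#' @return object of class `fluorescence_matrix`: a cells x frames numeric
#'   matrix with attributes `frame_rate_hz` and `kind = "raw"`.
#' @export
spikes_to_fluorescence <- function(trains, gamma = exp(-0.2), amplitude = 1,
                                   baseline = 1, noise_sd = 0.1,
                                   bleach_rate = 0, frame_rate_hz = 5,
                                   seed = 1L) {
  stopifnot(gamma > 0, gamma < 1, noise_sd >= 0, frame_rate_hz > 0,
            bleach_rate >= 0)
  dur <- trains[[1]]$duration_s
  n_frames <- floor(dur * frame_rate_hz)
  if (n_frames < 2) stop("need at least 2 frames", call. = FALSE)
  n <- length(trains)
  f <- matrix(0, n, n_frames)
  bleach <- exp(-bleach_rate * (seq_len(n_frames) - 1L))
  for (i in seq_len(n)) {
    counts <- tabulate(pmin(pmax(ceiling(trains[[i]]$times_s * frame_rate_hz),
                                 1L), n_frames), nbins = n_frames)
    c_t <- as.numeric(stats::filter(counts, gamma, method = "recursive"))
    f[i, ] <- amplitude * c_t * bleach + baseline
  }
  if (noise_sd > 0) {
    f <- f + with_seed(substream_seed(seed, 701L),
                       matrix(stats::rnorm(n * n_frames, 0, noise_sd),
                              n, n_frames))
  }
  fluorescence_matrix(f, frame_rate_hz, kind = "raw")
}

#' Fluorescence matrix container
#'
#' @param values cells x frames numeric matrix (no missing values, >= 2
#'   frames).
#' @param frame_rate_hz frames per second.
#' @param kind `"raw"` or `"corrected"` (dF/F).
#' @param epoch optional epoch tag.
#' @return the matrix with class `fluorescence_matrix` and the metadata as
#'   attributes.
#' @export
fluorescence_matrix <- function(values, frame_rate_hz = 5, kind = "raw",
                                epoch = NULL) {
  values <- as.matrix(values)
  if (ncol(values) < 2L) stop("need at least 2 frames", call. = FALSE)
  if (anyNA(values)) stop("fluorescence must not contain NA", call. = FALSE)
  structure(values, frame_rate_hz = frame_rate_hz, kind = kind, epoch = epoch,
            class = c("fluorescence_matrix", "matrix", "array"))
}

# paint filled disks onto a h x w canvas; returns matrix + overlap pixel count
.paint_disks <- function(h, w, cx, cy, radius, values, base = 0) {
  img <- matrix(base, h, w)
  hits <- matrix(0L, h, w)
  for (k in seq_along(cx)) {
    cols <- max(1L, floor(cx[k] + 1 - radius)):min(w, ceiling(cx[k] + 1 + radius))
    rows <- max(1L, floor(cy[k] + 1 - radius)):min(h, ceiling(cy[k] + 1 + radius))
    for (cc in cols) {
      dy2 <- radius^2 - (cc - 1 - cx[k])^2
      if (dy2 < 0) next
      rr <- rows[(rows - 1 - cy[k])^2 <= dy2]
      img[rr, cc] <- values[k]
      hits[rr, cc] <- hits[rr, cc] + 1L
    }
  }
  list(image = img, n_overlap_px = sum(hits > 1L))
}

#' Render synthetic nuclear/marker images and a calcium movie
#'
#' Paints one disk per ROI. The nuclear (DAPI-like) image is a bright-disk
#' image used to exercise segmentation; marker images paint each cell's
#' marker intensity; movie frames paint each ROI's fluorescence value on a
#' zero background (noise-free render), so the mean pixel value inside ROI i
#' at frame t equals `fluo[i, t]`. Overlapping disks are permitted but
#' flagged with a warning.
#'
#' @param culture a `synthetic_culture` (or any list with `roi_centroids`
#'   and `marker_intensities`).
#' @param fluo optional [fluorescence_matrix()]; when supplied a movie array
#'   (`frame_px` x `frame_px` x frames) is rendered.
#' @param frame_px image side in pixels (default 1007, the field geometry
#'   used throughout).
#' @param radius_px nuclear disk radius.
#' @param nuclear_value,nuclear_background intensities of the nuclear image.
#' @return list with `nuclear` (matrix), `markers` (list of matrices per
#'   channel), `label_image` (ground-truth ROI labels), and `movie` (array
#'   or `NULL`).
#' @export
render_synthetic_frames <- function(culture, fluo = NULL,
                                    frame_px = 1007L, radius_px = 8,
                                    nuclear_value = 0.9,
                                    nuclear_background = 0.05) {
  cx <- culture$roi_centroids$x
  cy <- culture$roi_centroids$y
  n <- length(cx)
  if (any(cx < 0 | cx > frame_px - 1 | cy < 0 | cy > frame_px - 1))
    stop("centroids outside the frame", call. = FALSE)
  nuc <- .paint_disks(frame_px, frame_px, cx, cy, radius_px,
                      rep(nuclear_value, n), base = nuclear_background)
  if (nuc$n_overlap_px > 0)
    warning(sprintf("%d pixels belong to overlapping nuclear disks",
                    nuc$n_overlap_px), call. = FALSE)
  lab <- .paint_disks(frame_px, frame_px, cx, cy, radius_px, seq_len(n))
  markers <- NULL
  mi <- culture$marker_intensities
  if (!is.null(mi)) {
    chans <- setdiff(names(mi), "roi_id")
    markers <- lapply(stats::setNames(chans, chans), function(ch)
      .paint_disks(frame_px, frame_px, cx, cy, radius_px, mi[[ch]])$image)
  }
  movie <- NULL
  if (!is.null(fluo)) {
    stopifnot(nrow(fluo) == n)
    movie <- array(0, c(frame_px, frame_px, ncol(fluo)))
    lab_img <- lab$image
    idx <- which(lab_img > 0)
    cell <- lab_img[idx]
    for (t in seq_len(ncol(fluo))) {
      fr <- matrix(0, frame_px, frame_px)
      fr[idx] <- fluo[cell, t]
      movie[, , t] <- fr
    }
  }
  list(nuclear = nuc$image, markers = markers,
       label_image = matrix(as.integer(lab$image), frame_px, frame_px),
       movie = movie)
}
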