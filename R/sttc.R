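#' Spike train object
#'
#' A spike train is a sorted vector of event times (seconds) over a known
#' recording duration; it is the unit of all correlation analysis.
#'
#' @param times_s numeric vector of spike times in seconds (any order;
#'   sorted on construction).
#' @param duration_s recording length in seconds (> 0).
#' @return an object of class `spike_train` with fields `times_s` and
#'   `duration_s`.
#' @examples
#' st <- spike_train(c(2.5, 1.0, 7.3), 60)
#' firing_rate(st)
#' @export
spike_train <- function(times_s, duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("`duration_s` must be a single positive number", call. = FALSE)
  times_s <- as.numeric(times_s)
  if (anyNA(times_s)) stop("spike times must not contain NA", call. = FALSE)
  if (any(times_s < 0 | times_s > duration_s))
    stop("spike times must lie in [0, duration_s]", call. = FALSE)
  structure(list(times_s = sort(times_s), duration_s = duration_s),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train: %d spikes over %g s (%.3g Hz)>\n",
              length(x$times_s), x$duration_s, firing_rate(x)))
  invisible(x)
}

is_spike_train <- function(x) inherits(x, "spike_train")

.sttc_eps <- 1e-12

#' Tiled time fraction T of a spike train
#'
#' Proportion of the total recording time lying within +/- `delta_t_s` of any
#' spike: the measure of the union of the tiles `[t - dt, t + dt]`, clipped at
#' the recording boundaries, divided by the recording duration. This is the
#' T_A / T_B term of the spike time tiling coefficient.
#'
#' @param train a [spike_train()].
#' @param delta_t_s tiling half-window in seconds (default 0.05, i.e. the
#'   50 ms used throughout the analysis).
#' @return a proportion in `[0, 1]`; 0 for an empty train.
#' @export
tiled_time_fraction <- function(train, delta_t_s = 0.05) {
  stopifnot(is_spike_train(train), delta_t_s > 0)
  t <- train$times_s
  if (length(t) == 0L) return(0)
  d <- train$duration_s
  s <- pmax(t - delta_t_s, 0)
  e <- pmin(t + delta_t_s, d)
  # t sorted => e nondecreasing; overlap-merge via the previous tile end
  prev_end <- c(-Inf, e[-length(e)])
  sum(pmax(0, e - pmax(s, prev_end))) / d
}

#' Tiled spike proportion P between two trains
#'
#' Fraction of spikes of `a` lying within +/- `delta_t_s` of any spike of
#' `b`: the P_A / P_B term of the spike time tiling coefficient.
#'
#' @param a,b [spike_train()] objects; `a` must be non-empty.
#' @param delta_t_s tiling half-window in seconds.
#' @return a proportion in `[0, 1]`, or `NA` (with a warning) if `a` is empty.
#' @export
tiled_spike_proportion <- function(a, b, delta_t_s = 0.05) {
  stopifnot(is_spike_train(a), is_spike_train(b), delta_t_s > 0)
  ta <- a$times_s
  tb <- b$times_s
  if (length(ta) == 0L) {
    warning("tiled spike proportion undefined for an empty train")
    return(NA_real_)
  }
  if (length(tb) == 0L) return(0)
  mean(.min_dist_to(ta, tb) <= delta_t_s + .sttc_eps)
}

# minimum |x - y| for each x against sorted y
.min_dist_to <- function(x, y) {
  i <- findInterval(x, y)
  lo <- ifelse(i >= 1L, y[pmax(i, 1L)], Inf)
  hi <- ifelse(i < length(y), y[pmin(i + 1L, length(y))], Inf)
  pmin(abs(x - lo), abs(hi - x))
}

#' Spike time tiling coefficient (STTC)
#'
#' Firing-rate-insensitive pairwise spike-train correlation:
#' \deqn{STTC = \frac{1}{2}\left(\frac{P_A - T_B}{1 - P_A T_B} +
#'   \frac{P_B - T_A}{1 - P_B T_A}\right)}
#' where T is the tiled time fraction and P the tiled spike proportion with
#' half-window `delta_t_s`. An STTC value between a neuron pair is the
#' analysis' correlation index (CI); identical non-degenerate trains score
#' exactly +1.
#'
#' @inheritParams tiled_spike_proportion
#' @return a value in `[-1, 1]`, or `NA` when undefined (either train empty,
#'   or a denominator degenerate); undefined pairs are excluded downstream.
#' @examples
#' a <- spike_train(c(1.0, 2.5, 7.3), 60)
#' sttc(a, a)                      # +1 exactly
#' sttc(a, spike_train(10, 60))    # slightly negative
#' @export
sttc <- function(a, b, delta_t_s = 0.05) {
  stopifnot(is_spike_train(a), is_spike_train(b))
  if (!isTRUE(all.equal(a$duration_s, b$duration_s)))
    stop("spike trains must share a recording duration", call. = FALSE)
  if (length(a$times_s) == 0L || length(b$times_s) == 0L) return(NA_real_)
  ta <- tiled_time_fraction(a, delta_t_s)
  tb <- tiled_time_fraction(b, delta_t_s)
  pa <- mean(.min_dist_to(a$times_s, b$times_s) <= delta_t_s + .sttc_eps)
  pb <- mean(.min_dist_to(b$times_s, a$times_s) <= delta_t_s + .sttc_eps)
  .sttc_from_terms(pa, pb, ta, tb)
}

.sttc_from_terms <- function(pa, pb, ta, tb) {
  d1 <- 1 - pa * tb
  d2 <- 1 - pb * ta
  if (abs(d1) <= .sttc_eps || abs(d2) <= .sttc_eps) return(NA_real_)
  0.5 * ((pa - tb) / d1 + (pb - ta) / d2)
}

#' Pairwise STTC adjacency matrix for one epoch
#'
#' Computes the STTC between all neuron pairs and stores them in a symmetric
#' `n x n` matrix (the epoch's CI matrix). The diagonal is `NA` and is
#' excluded from all summaries; pairs whose STTC is undefined (empty train or
#' degenerate denominator) are stored as `NA`.
#'
#' @param trains list of [spike_train()] objects over a common duration.
#' @param delta_t_s tiling half-window in seconds.
#' @param epoch optional epoch tag stored as an attribute.
#' @return symmetric numeric matrix with attribute `epoch`.
#' @export
adjacency_matrix <- function(trains, delta_t_s = 0.05, epoch = NULL) {
  stopifnot(is.list(trains), length(trains) >= 2L)
  ok <- vapply(trains, is_spike_train, logical(1))
  if (!all(ok)) stop("all elements of `trains` must be spike_train objects",
                     call. = FALSE)
  dur <- vapply(trains, `[[`, numeric(1), "duration_s")
  if (max(dur) - min(dur) > 1e-9)
    stop("all spike trains must share a recording duration", call. = FALSE)
  n <- length(trains)
  tt <- vapply(trains, tiled_time_fraction, numeric(1), delta_t_s = delta_t_s)
  nspk <- vapply(trains, function(s) length(s$times_s), integer(1))
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1L)) {
    if (nspk[i] == 0L) next
    ti <- trains[[i]]$times_s
    for (j in seq.int(i + 1L, n)) {
      if (nspk[j] == 0L) next
      tj <- trains[[j]]$times_s
      pa <- mean(.min_dist_to(ti, tj) <= delta_t_s + .sttc_eps)
      pb <- mean(.min_dist_to(tj, ti) <= delta_t_s + .sttc_eps)
      m[i, j] <- m[j, i] <- .sttc_from_terms(pa, pb, tt[i], tt[j])
    }
  }
  if (!is.null(names(trains))) dimnames(m) <- list(names(trains), names(trains))
  attr(m, "epoch") <- epoch
  attr(m, "delta_t_s") <- delta_t_s
  m
}
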