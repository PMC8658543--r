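#' Total flow (node strength) of an adjacency matrix
#'
#' Strength of node i is the sum of all CI values incident to it; missing
#' (undefined) entries contribute 0 and the diagonal is excluded. Negative CI
#' values are retained here — the network is undirected and both positive and
#' negative correlations carry information; the ICD survival analysis floors
#' them separately.
#'
#' @param m adjacency matrix from [adjacency_matrix()].
#' @param breaks optional break specification for an attached histogram
#'   (passed to [hist()]).
#' @return numeric vector of node strengths; when `breaks` is supplied the
#'   histogram (`hist` object, `plot = FALSE`) is attached as attribute
#'   `"histogram"`.
#' @export
total_flow <- function(m, breaks = NULL) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  mm <- m
  diag(mm) <- NA_real_
  s <- rowSums(mm, na.rm = TRUE)
  if (!is.null(breaks))
    attr(s, "histogram") <- hist(s, breaks = breaks, plot = FALSE)
  s
}

#' Group-wise mean CI
#'
#' Means of the CI (STTC) over neuron-pair sets defined by marker labels.
#' Grouping `"neun_arc"` restricts to NeuN-positive cells and yields the
#' three sets Arc-Arc, Arc-NeuN (one Arc-positive, one Arc-negative) and
#' NeuN-NeuN (both Arc-negative). Grouping `"arc_cfos"` uses the four
#' Arc/c-Fos combinatorial groups and yields the 10 unordered group-pair
#' sets. Means are taken over defined (non-missing) off-diagonal entries
#' only; an empty set yields `NA` with a warning.
#'
#' @param m adjacency matrix (rows aligned with `labels` rows).
#' @param labels data frame from [assign_labels()] with columns `neun_pos`,
#'   `arc_pos`, `cfos_pos`, `group`.
#' @param grouping `"neun_arc"` or `"arc_cfos"`.
#' @return data frame with columns `set`, `mean_ci`, `n_pairs`.
#' @export
group_mean_ci <- function(m, labels, grouping = c("neun_arc", "arc_cfos")) {
  grouping <- match.arg(grouping)
  stopifnot(is.matrix(m), nrow(m) == nrow(labels))
  if (grouping == "neun_arc") {
    keep <- which(labels$neun_pos)
    arc <- labels$arc_pos[keep]
    sets <- list(
      `Arc-Arc`   = outer(arc, arc, `&`),
      `Arc-NeuN`  = outer(arc, !arc, `&`) | outer(!arc, arc, `&`),
      `NeuN-NeuN` = outer(!arc, !arc, `&`)
    )
    sub <- m[keep, keep, drop = FALSE]
  } else {
    keep <- which(labels$neun_pos & !is.na(labels$group))
    grp <- as.character(labels$group[keep])
    lev <- c("Arc+cFos+", "Arc+cFos-", "Arc-cFos+", "Arc-cFos-")
    pairs <- utils::combn(seq_along(lev), 2, simplify = FALSE)
    pairs <- c(lapply(seq_along(lev), function(i) c(i, i)), pairs)
    sets <- lapply(pairs, function(p) {
      outer(grp == lev[p[1]], grp == lev[p[2]], `&`) |
        outer(grp == lev[p[2]], grp == lev[p[1]], `&`)
    })
    names(sets) <- vapply(pairs, function(p)
      paste(lev[p[1]], lev[p[2]], sep = "|"), character(1))
    sub <- m[keep, keep, drop = FALSE]
  }
  if (length(keep)) diag(sub) <- NA_real_
  res <- lapply(names(sets), function(nm) {
    sel <- sets[[nm]]
    vals <- sub[sel & !is.na(sub)]
    if (length(vals) == 0L) {
      warning(sprintf("no defined pairs in set '%s'", nm), call. = FALSE)
      data.frame(set = nm, mean_ci = NA_real_, n_pairs = 0L)
    } else {
      # each unordered pair appears twice in the symmetric selection
      data.frame(set = nm, mean_ci = mean(vals), n_pairs = length(vals) %/% 2L)
    }
  })
  do.call(rbind, res)
}

#' Classify correlation changes between two epochs
#'
#' Positive-change pairs move from low CI at baseline (`[0, 0.5)`) to high CI
#' after stimulation (`[0.5, 1]`); negative-change pairs make the mirrored
#' move from `[0.5, 1]` down to `[0, 0.5)`. All other defined pairs are
#' `"none"`; pairs undefined in either epoch are dropped.
#'
#' @param m_before,m_after adjacency matrices sharing neuron order.
#' @param labels optional label data frame (adds `arc_arc` and `pair_type`).
#' @param centroids optional 2-column matrix of ROI centroids in pixels
#'   (adds `distance_um`).
#' @param pixel_size_um physical pixel size (default 0.8).
#' @return data frame of pair records: `i`, `j`, `ci_before`, `ci_after`,
#'   `change_class` and the optional columns above.
#' @export
classify_correlation_changes <- function(m_before, m_after, labels = NULL,
                                         centroids = NULL,
                                         pixel_size_um = 0.8) {
  stopifnot(is.matrix(m_before), all(dim(m_before) == dim(m_after)))
  n <- nrow(m_before)
  idx <- which(upper.tri(m_before), arr.ind = TRUE)
  rec <- data.frame(i = idx[, 1], j = idx[, 2],
                    ci_before = m_before[idx], ci_after = m_after[idx])
  rec <- rec[!is.na(rec$ci_before) & !is.na(rec$ci_after), , drop = FALSE]
  pos <- rec$ci_before >= 0 & rec$ci_before < 0.5 &
    rec$ci_after >= 0.5 & rec$ci_after <= 1
  neg <- rec$ci_before >= 0.5 & rec$ci_before <= 1 &
    rec$ci_after >= 0 & rec$ci_after < 0.5
  rec$change_class <- ifelse(pos, "positive", ifelse(neg, "negative", "none"))
  if (!is.null(labels)) {
    stopifnot(nrow(labels) == n)
    arc <- labels$arc_pos
    rec$arc_arc <- arc[rec$i] & arc[rec$j]
    tag <- ifelse(arc, "Arc+", "Arc-")
    rec$pair_type <- paste(pmin(tag[rec$i], tag[rec$j]),
                           pmax(tag[rec$i], tag[rec$j]), sep = "|")
  }
  if (!is.null(centroids)) {
    stopifnot(nrow(centroids) == n)
    d <- sqrt((centroids[rec$i, 1] - centroids[rec$j, 1])^2 +
                (centroids[rec$i, 2] - centroids[rec$j, 2])^2)
    rec$distance_um <- d * pixel_size_um
  }
  rownames(rec) <- NULL
  rec
}

#' Arc-Arc pair fraction versus CI threshold
#'
#' For each threshold, the fraction of qualifying change pairs whose both
#' endpoints are Arc-positive. Positive-change pairs qualify by their final
#' CI, negative-change pairs by their initial CI (the convention of the
#' change analysis).
#'
#' @param records data frame from [classify_correlation_changes()] built with
#'   labels (must contain `arc_arc`).
#' @param thresholds ascending numeric CI thresholds.
#' @return data frame with `change_class`, `threshold`, `n_pairs`,
#'   `frac_arc_arc` (`NA` where no pair qualifies).
#' @export
arc_pair_fraction_vs_threshold <- function(records,
                                           thresholds = seq(0, 1, by = 0.05)) {
  stopifnot(nrow(records) > 0, "arc_arc" %in% names(records))
  out <- lapply(c("positive", "negative"), function(cls) {
    sub <- records[records$change_class == cls, , drop = FALSE]
    ci <- if (cls == "positive") sub$ci_after else sub$ci_before
    do.call(rbind, lapply(thresholds, function(th) {
      q <- ci >= th
      data.frame(change_class = cls, threshold = th, n_pairs = sum(q),
                 frac_arc_arc = if (any(q)) mean(sub$arc_arc[q]) else NA_real_)
    }))
  })
  do.call(rbind, out)
}

#' Pairwise physical distances between ROI centroids
#'
#' Euclidean centroid distances scaled to micrometres (0.8 um per pixel for
#' the 1007 x 1007 px field used throughout).
#'
#' @param centroids 2-column matrix/data frame of (x, y) pixel coordinates.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return symmetric matrix of distances in micrometres.
#' @export
pair_distances <- function(centroids, pixel_size_um = 0.8) {
  centroids <- as.matrix(centroids)
  stopifnot(ncol(centroids) == 2, pixel_size_um > 0)
  as.matrix(stats::dist(centroids)) * pixel_size_um
}

#' Mean pair distance above CI thresholds
#'
#' Average physical distance of all neuronal pairs whose CI exceeds each
#' threshold value.
#'
#' @param m adjacency matrix.
#' @param dist_um distance matrix from [pair_distances()] (same order).
#' @param thresholds ascending CI thresholds.
#' @return data frame with `threshold`, `n_pairs`, `mean_distance_um`.
#' @export
mean_distance_above_threshold <- function(m, dist_um,
                                          thresholds = seq(0, 0.9, by = 0.1)) {
  stopifnot(all(dim(m) == dim(dist_um)))
  ut <- upper.tri(m)
  ci <- m[ut]
  d <- dist_um[ut]
  ok <- !is.na(ci)
  do.call(rbind, lapply(thresholds, function(th) {
    q <- ok & ci > th
    data.frame(threshold = th, n_pairs = sum(q),
               mean_distance_um = if (any(q)) mean(d[q]) else NA_real_)
  }))
}

#' Histogram-based (nonkernel) probability density estimate
#'
#' Density of a sample over explicit bins, normalized so the bin-integral is
#' exactly 1. Constant samples collapse to a single bin carrying all mass.
#'
#' @param values numeric vector (length >= 1).
#' @param breaks bin specification: a count, a breaks vector, or an algorithm
#'   name as accepted by [hist()].
#' @return data frame with `mid`, `density`, `width`, `count`.
#' @export
density_distribution <- function(values, breaks = "Sturges") {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1)
  if (diff(range(values)) == 0) {
    w <- max(abs(values[1]) * 0.01, 0.01)
    breaks <- c(values[1] - w / 2, values[1] + w / 2)
  }
  h <- hist(values, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, density = h$density,
             width = diff(h$breaks), count = h$counts)
}
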