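#' ROI set from a label image
#'
#' Wraps an integer label image (0 = background, k > 0 = ROI k) together with
#' per-ROI centroids and areas. Coordinates are 0-based with x = column,
#' y = row, the convention used by the distance analysis.
#'
#' @param label_image integer matrix of ROI labels.
#' @return object of class `roi_set` with fields `label_image`, `roi_id`,
#'   `centroid_x`, `centroid_y`, `area_px`.
#' @export
roi_set <- function(label_image) {
  label_image <- as.matrix(label_image)
  ids <- sort(unique(as.integer(label_image[label_image > 0])))
  if (length(ids)) {
    idx <- which(label_image > 0, arr.ind = TRUE)
    lab <- label_image[label_image > 0]
    cx <- tapply(idx[, "col"] - 1, lab, mean)   # x = column, 0-based
    cy <- tapply(idx[, "row"] - 1, lab, mean)   # y = row, 0-based
    area <- tapply(lab, lab, length)
    o <- match(as.character(ids), names(cx))
    cx <- as.numeric(cx[o]); cy <- as.numeric(cy[o])
    area <- as.integer(area[o])
  } else {
    cx <- cy <- numeric(0); area <- integer(0)
  }
  structure(list(label_image = label_image, roi_id = ids,
                 centroid_x = cx, centroid_y = cy, area_px = area),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set: %d ROIs on a %d x %d image>\n",
              length(x$roi_id), nrow(x$label_image), ncol(x$label_image)))
  invisible(x)
}

#' Segment nuclei from a nuclear-stain image
#'
#' Global Otsu threshold, connected-component labelling, then an area filter.
#' No watershed splitting of touching nuclei is attempted.
#'
#' @param image 2-D numeric matrix (grayscale nuclear channel, e.g. DAPI).
#' @param min_area_px,max_area_px inclusive area filter in pixels.
#' @param threshold optional manual threshold on the original intensity
#'   scale; when `NULL` (default) Otsu's method chooses it.
#' @return a [roi_set()] (empty for a blank image).
#' @export
segment_nuclei <- function(image, min_area_px = 50, max_area_px = 5000,
                           threshold = NULL) {
  image <- as.matrix(image)
  rng <- range(image)
  if (is.null(threshold)) {
    if (diff(rng) == 0) return(roi_set(matrix(0L, nrow(image), ncol(image))))
    norm <- (image - rng[1]) / diff(rng)
    thr01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    bw <- norm > thr01
  } else {
    bw <- image > threshold
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  lab <- matrix(as.integer(lab), nrow(image), ncol(image))
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= min_area_px & areas <= max_area_px)
    remap <- integer(length(areas))
    remap[keep] <- seq_along(keep)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  roi_set(lab)
}

#' Mean marker intensity within each ROI
#'
#' @param image 2-D numeric matrix of the marker channel; must match the ROI
#'   label image dimensions.
#' @param rois a [roi_set()].
#' @return numeric vector of per-ROI mean intensities, in `rois$roi_id` order.
#' @export
quantify_roi_intensity <- function(image, rois) {
  stopifnot(inherits(rois, "roi_set"))
  image <- as.matrix(image)
  if (!all(dim(image) == dim(rois$label_image)))
    stop("image dimensions do not cover the ROI masks", call. = FALSE)
  if (length(rois$roi_id) == 0L) return(numeric(0))
  lab <- rois$label_image
  m <- tapply(image[lab > 0L], lab[lab > 0L], mean)
  as.numeric(m[match(as.character(rois$roi_id), names(m))])
}

#' Assign marker labels and combinatorial groups
#'
#' A cell is positive for a channel when its intensity is strictly above that
#' channel's threshold. The Arc/c-Fos combinatorial group is defined only on
#' NeuN-positive cells; non-neuronal ROIs are excluded from all downstream
#' neuron-level analyses.
#'
#' @param intensities data frame with columns `roi_id`, `neun`, `arc`,
#'   `cfos` (mean intensities).
#' @param thresholds named list/vector with entries `neun`, `arc`, `cfos`.
#' @return data frame with `roi_id`, `neun_pos`, `arc_pos`, `cfos_pos` and
#'   `group` (one of `"Arc+cFos+"`, `"Arc+cFos-"`, `"Arc-cFos+"`,
#'   `"Arc-cFos-"`, or `NA` for NeuN-negative ROIs).
#' @export
assign_labels <- function(intensities, thresholds) {
  need <- c("neun", "arc", "cfos")
  if (!all(need %in% names(intensities)))
    stop("intensity table must have channels: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(need %in% names(thresholds)))
    stop("missing threshold for channel(s): ",
         paste(setdiff(need, names(thresholds)), collapse = ", "),
         call. = FALSE)
  neun_pos <- intensities$neun > thresholds[["neun"]]
  arc_pos <- intensities$arc > thresholds[["arc"]]
  cfos_pos <- intensities$cfos > thresholds[["cfos"]]
  group <- ifelse(neun_pos,
                  paste0("Arc", ifelse(arc_pos, "+", "-"),
                         "cFos", ifelse(cfos_pos, "+", "-")),
                  NA_character_)
  data.frame(roi_id = intensities$roi_id, neun_pos = neun_pos,
             arc_pos = arc_pos, cfos_pos = cfos_pos, group = group)
}
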