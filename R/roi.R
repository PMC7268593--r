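# Detection of candidate spherical objects in corrected phase images.
#
# The phase is binarized at a configurable threshold, 4-connected components
# are labeled (holes filled before measuring, so ring-like interiors such as
# nucleoli-induced dips do not split an object), components are kept whose
# equivalent diameter matches the expected specimen size within a relative
# variation, and padded bounding boxes become regions of interest with
# stable, reproducible identifiers "<dataset>_<image>.<roi>".

#' Compute a binarization threshold for object detection
#'
#' Methods: a numeric value is passed through unchanged; `"otsu"` is the
#' bimodal histogram threshold over 256 bins; `"dm-nuclei"` disregards the
#' top 1% of the phase values and places the threshold at 20% of the
#' resulting maximum relative to the mean of the original phase:
#' `t = mean(phase) + 0.2 (P99 - mean(phase))`, with `P99` the maximum after
#' trimming the top percent (type-1 quantile).  Designed for low-index
#' objects containing small high-index inclusions, where plain Otsu either
#' fails or segments only the inclusions.
#'
#' @param phase phase matrix, radians.
#' @param method `"otsu"`, `"dm-nuclei"`, or a numeric threshold.
#' @return Threshold value (radians).
#' @export
compute_threshold <- function(phase, method = "otsu") {
  stopifnot(all(is.finite(phase)))
  if (is.numeric(method)) return(method)
  switch(method,
    "otsu" = {
      rg <- range(phase)
      if (rg[1] == rg[2]) return(rg[1])
      EBImage::otsu(phase, range = rg, levels = 256L)
    },
    "dm-nuclei" = {
      m <- mean(phase)
      p99 <- unname(stats::quantile(phase, 0.99, type = 1, names = FALSE))
      m + 0.2 * (p99 - m)
    },
    stop("unknown threshold method: ", method))
}

.roi_identifier <- function(dataset, image_index, roi_index) {
  sprintf("%s_%d.%d", dataset, image_index, roi_index)
}

#' Find regions of interest around phase objects
#'
#' Binarizes `phase > threshold`, labels 4-connected components (holes
#' filled), keeps components whose equivalent diameter
#' `d = 2 sqrt(area / pi)` satisfies `|d - size_px| <= variation * size_px`
#' (boundary inclusive), and returns their bounding boxes expanded by
#' `pad_px` and clipped to the image.  ROIs are ordered and numbered 1..K by
#' their top-left corner `(r0, c0)`.
#'
#' @param phase background-corrected phase matrix.
#' @param size_px expected object diameter in pixels (>= 5).
#' @param variation allowed relative deviation of the equivalent diameter,
#'   in (0, 1).
#' @param pad_px bounding-box padding in pixels.
#' @param threshold_method see [compute_threshold()].
#' @param exclude_border_px components with any pixel closer than this to
#'   the image border are discarded (edge artifacts and clipped objects
#'   cannot be fitted reliably).
#' @param image_index 1-based index of the image in its series.
#' @param dataset dataset identifier used in ROI identifiers.
#' @return List of `roi` objects (fields `image_index`, `roi_index`,
#'   `r0`, `r1`, `c0`, `c1` as 0-based half-open bounds, `identifier`).
#' @export
find_rois <- function(phase, size_px, variation = 0.5, pad_px = 10L,
                      threshold_method = "otsu", exclude_border_px = 5L,
                      image_index = 1L, dataset = "00000") {
  stopifnot(size_px >= 5, variation > 0, variation < 1)
  t <- compute_threshold(phase, threshold_method)
  mask <- phase > t
  if (!any(mask)) return(list())
  lab <- EBImage::bwlabel(mask)           # 4-connected labeling
  lab <- EBImage::fillHull(lab)           # fill holes within components
  nlab <- max(lab)
  keep <- list()
  eb <- exclude_border_px
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    d <- 2 * sqrt(nrow(idx) / pi)
    if (abs(d - size_px) > variation * size_px) next
    if (eb > 0 && (min(idx) <= eb || max(idx[, 1]) > nrow(phase) - eb ||
                   max(idx[, 2]) > ncol(phase) - eb)) next
    r0 <- min(idx[, 1]) - 1L; r1 <- max(idx[, 1])  # 0-based half-open
    c0 <- min(idx[, 2]) - 1L; c1 <- max(idx[, 2])
    r0 <- max(0L, r0 - pad_px); c0 <- max(0L, c0 - pad_px)
    r1 <- min(nrow(phase), r1 + pad_px); c1 <- min(ncol(phase), c1 + pad_px)
    keep[[length(keep) + 1L]] <- list(r0 = r0, r1 = r1, c0 = c0, c1 = c1)
  }
  if (!length(keep)) return(list())
  ord <- order(vapply(keep, `[[`, 0L, "r0"), vapply(keep, `[[`, 0L, "c0"))
  out <- vector("list", length(keep))
  for (k in seq_along(ord)) {
    b <- keep[[ord[k]]]
    out[[k]] <- structure(
      list(image_index = as.integer(image_index), roi_index = k,
           r0 = b$r0, r1 = b$r1, c0 = b$c0, c1 = b$c1,
           identifier = .roi_identifier(dataset, image_index, k)),
      class = "roi")
  }
  out
}

#' Drop user-excluded ROIs
#'
#' Removes ROIs whose `(image_index, roi_index)` pair appears in the ignore
#' list.  Remaining ROIs keep their indices and identifiers (no renumbering),
#' so identifiers stay stable across reruns.  Ignore entries matching no ROI
#' produce a warning, not an error.
#'
#' @param rois list of `roi` objects.
#' @param ignore list of `c(image, roi)` integer pairs (or an n-by-2 matrix).
#' @return Filtered list of ROIs.
#' @export
filter_ignored <- function(rois, ignore) {
  if (is.matrix(ignore)) ignore <- split(ignore, row(ignore))
  if (!length(ignore)) return(rois)
  keys <- vapply(rois, function(r) sprintf("%d.%d", r$image_index, r$roi_index), "")
  ign <- vapply(ignore, function(p) sprintf("%d.%d", p[1], p[2]), "")
  unmatched <- setdiff(ign, keys)
  if (length(unmatched))
    warning("ignore entries matched no ROI: ", paste(unmatched, collapse = ", "))
  rois[!(keys %in% ign)]
}

#' Extract and background-correct one ROI
#'
#' Crops phase and amplitude to the ROI bounds, applies the per-ROI
#' background correction and copies the acquisition metadata; the result's
#' identifier is the ROI identifier.
#'
#' @param qpi source [qpimage()].
#' @param roi an `roi` object.
#' @param spec a [bg_spec()] for the per-ROI correction, or `NULL` to skip.
#' @return Cropped (and corrected) [qpimage()].
#' @export
extract_roi <- function(qpi, roi, spec = NULL) {
  H <- nrow(qpi$phase); W <- ncol(qpi$phase)
  if (roi$r0 < 0 || roi$c0 < 0 || roi$r1 > H || roi$c1 > W ||
      roi$r0 >= roi$r1 || roi$c0 >= roi$c1)
    stop("ROI exceeds image bounds")
  rows <- (roi$r0 + 1):roi$r1; cols <- (roi$c0 + 1):roi$c1
  out <- qpimage(qpi$phase[rows, cols], qpi$amplitude[rows, cols],
                 qpi$wavelength, qpi$pixel_size, qpi$medium_index,
                 time = qpi$time, identifier = roi$identifier)
  if (!is.null(spec)) out <- correct_background(out, spec)
  out
}
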