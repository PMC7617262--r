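#' Tissue names used throughout the package
#'
#' The eight labelled tissues of the neonatal relaxometry slice, in label
#' order (label 0 is background). PVFWM is periventricular frontal white
#' matter, which appears T2-hyperintense in infants and takes priority over
#' overlapping labels when maps are composited.
#'
#' @return Named integer vector mapping tissue name to label value.
#' @export
tissue_labels <- function() {
  c(cortical_gm = 1L, white_matter = 2L, brainstem = 3L, cerebellum = 4L,
    cerebellar_vermis = 5L, basal_ganglia = 6L, thalamus = 7L, pvfwm = 8L)
}

#' Construct a label map
#'
#' @param labels Integer matrix of per-pixel labels (0 = background).
#' @param tissue_names Named integer vector mapping names to label values.
#' @return A list of class `label_map`.
#' @export
label_map <- function(labels, tissue_names = tissue_labels()) {
  stopifnot(is.matrix(labels))
  bad <- setdiff(unique(as.vector(labels)), c(0L, unname(tissue_names)))
  if (length(bad)) stop("labels contain values without tissue names: ",
                        paste(bad, collapse = ", "))
  structure(list(labels = labels, tissue_names = tissue_names),
            class = "label_map")
}

#' Erode every tissue label by one pixel
#'
#' Each label region is eroded independently with a 3x3 square structuring
#' element (background grows), then the regions are re-composited in label
#' order with PVFWM applied last so it keeps priority over any overlap.
#' Reduces partial-volume contamination at region borders.
#'
#' @param lm A `label_map`.
#' @return The eroded `label_map`.
#' @export
erode_labels <- function(lm) {
  stopifnot(inherits(lm, "label_map"))
  kern <- matrix(1, 3, 3)
  out <- matrix(0L, nrow(lm$labels), ncol(lm$labels))
  ord <- lm$tissue_names
  if ("pvfwm" %in% names(ord))
    ord <- c(ord[setdiff(names(ord), "pvfwm")], ord["pvfwm"])
  for (id in ord) {
    m <- (lm$labels == id) * 1
    if (!any(m > 0)) next
    er <- EBImage::erode(m, kern)
    out[er > 0.5] <- id
  }
  label_map(out, lm$tissue_names)
}

#' Median parameter value per tissue region
#'
#' Medians are taken over valid pixels of each labelled region; tissues with
#' fewer than `min_pixels` valid pixels are reported with `NA` medians
#' (small structures are often absent from the single imaged slice) but keep
#' their pixel counts.
#'
#' @param values Numeric matrix of a fitted parameter (e.g. `t1_ms`).
#' @param lm A `label_map` sharing the matrix geometry.
#' @param min_pixels Minimum valid pixels for a reportable median.
#' @param valid Optional logical matrix of per-pixel validity (QC pass).
#' @return Data frame: `tissue`, `median`, `n_pixels`.
#' @export
summarize_roi <- function(values, lm, min_pixels = 10, valid = NULL) {
  stopifnot(inherits(lm, "label_map"))
  if (!all(dim(values) == dim(lm$labels)))
    stop("parameter map and label map geometries do not match")
  if (is.null(valid)) valid <- !is.na(values)
  if (!all(dim(valid) == dim(values))) stop("valid mask geometry mismatch")
  res <- lapply(names(lm$tissue_names), function(tn) {
    sel <- lm$labels == lm$tissue_names[[tn]] & valid & !is.na(values)
    n <- sum(sel)
    data.frame(tissue = tn,
               median = if (n >= min_pixels) stats::median(values[sel]) else NA_real_,
               n_pixels = n)
  })
  do.call(rbind, res)
}

#' Extract a 2D label slice from a 3D label volume
#'
#' Nearest-neighbour resampling of integer labels onto the mapping-slice
#' grid (labels must not be interpolated).
#'
#' @param labels_3d 3D integer array of labels.
#' @param vg The volume's `vol_geometry`.
#' @param sg The target `slice_geometry`.
#' @param tissue_names Label-name table for the output map.
#' @return A `label_map`; out-of-volume pixels become background.
#' @export
extract_slice <- function(labels_3d, vg, sg, tissue_names = tissue_labels()) {
  stopifnot(length(dim(labels_3d)) == 3, inherits(vg, "vol_geometry"),
            inherits(sg, "slice_geometry"))
  idx <- round(.world_to_index(.slice_world_coords(sg), vg))
  d <- dim(labels_3d)
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
    idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  vals <- integer(nrow(idx))
  vals[inside] <- labels_3d[idx[inside, , drop = FALSE]]
  if (!any(inside)) stop("slice geometry is disjoint from the label volume")
  label_map(matrix(vals, sg$dims[1], sg$dims[2]), tissue_names)
}
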