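#' Write a simulated exam to disk as a NIfTI + JSON directory
#'
#' Emits the inversion-recovery stack, the multi-TE TSE stack, the AFI
#' volume pair, the label map and the ground truth, together with a
#' manifest JSON tying them together. All images are NIfTI; timing sidecars
#' are JSON with times in SI seconds (fields in ms suffixed `_ms`).
#'
#' @param dir Output directory (created if needed).
#' @param truth A `phantom_truth`.
#' @param ir Output of [simulate_ir_series()] (or `NULL` to omit).
#' @param tse Output of [simulate_tse_series()] (or `NULL`).
#' @param afi Output of [simulate_afi_pair()] (or `NULL`; a missing AFI
#'   means T2 cannot be estimated for this exam).
#' @param subject_id,exam_id Identifiers recorded in the manifest.
#' @param seed Generation seed recorded in the manifest.
#' @return The manifest path, invisibly.
#' @export
write_exam <- function(dir, truth, ir = NULL, tse = NULL, afi = NULL,
                       subject_id = 1L, exam_id = 1L, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  px <- truth$spec$pixel_mm
  man <- list(subject_id = subject_id, exam_id = exam_id, seed = seed,
              pixel_mm = px, shape = truth$spec$shape,
              pma_weeks = truth$spec$pma_weeks)
  wn <- function(arr, name, pixdim) {
    path <- file.path(dir, name)
    img <- RNifti::asNifti(arr, pixdim = pixdim)
    RNifti::writeNifti(img, path)
    name
  }
  man$labels <- wn(truth$labels$labels, "labels.nii.gz", c(px, px))
  man$tissue_names <- as.list(truth$labels$tissue_names)
  man$truth <- list(
    t1 = wn(truth$t1_ms, "truth_t1_ms.nii.gz", c(px, px)),
    t2 = wn(truth$t2_ms, "truth_t2_ms.nii.gz", c(px, px)),
    eps = wn(truth$eps, "truth_eps.nii.gz", c(px, px)),
    s0 = wn(truth$s0, "truth_s0.nii.gz", c(px, px)),
    b1rel = wn(truth$b1rel, "truth_b1rel.nii.gz", c(px, px)))
  if (!is.null(ir)) {
    man$ir <- list(stack = wn(ir$images, "ir_stack.nii.gz", c(px, px, 1)),
                   ti_s = ir$ti_s, sigma = ir$sigma)
  }
  if (!is.null(tse)) {
    man$tse <- list(stack = wn(tse$images, "tse_stack.nii.gz", c(px, px, 1)),
                    te_ms = tse$te_ms, sigma = tse$sigma)
  }
  if (!is.null(afi)) {
    sp <- afi$geometry$spacing_mm
    man$afi <- list(s1 = wn(afi$s1, "afi_s1.nii.gz", sp),
                    s2 = wn(afi$s2, "afi_s2.nii.gz", sp),
                    origin_mm = afi$geometry$origin_mm,
                    spacing_mm = sp,
                    theta_nominal_deg = afi$theta_nominal_deg,
                    tr_ratio = afi$tr_ratio)
  }
  path <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, digits = NA, null = "null",
                              pretty = TRUE), path)
  invisible(path)
}

#' Read an exam manifest and its referenced images
#'
#' Validates that referenced files exist and that timing sidecars match the
#' stack sizes.
#'
#' @param dir Exam directory containing `manifest.json`.
#' @return A list mirroring the written exam: identifiers, arrays and
#'   sidecar metadata.
#' @export
read_exam <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  man <- jsonlite::fromJSON(mpath)
  rd <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop("manifest references a missing file: ", p)
    arr <- as.array(RNifti::readNifti(p))
    arr
  }
  out <- list(subject_id = man$subject_id, exam_id = man$exam_id,
              seed = man$seed, pixel_mm = man$pixel_mm,
              pma_weeks = man$pma_weeks,
              labels = label_map(matrix(as.integer(rd(man$labels)),
                                        man$shape[1], man$shape[2]),
                                 unlist(man$tissue_names)),
              truth = lapply(man$truth, rd))
  if (!is.null(man$ir)) {
    stack <- rd(man$ir$stack)
    if (dim(stack)[3] != length(man$ir$ti_s))
      stop("IR sidecar length does not match stack in ", mpath)
    out$ir <- list(images = stack, ti_s = man$ir$ti_s, sigma = man$ir$sigma)
  }
  if (!is.null(man$tse)) {
    stack <- rd(man$tse$stack)
    if (dim(stack)[3] != length(man$tse$te_ms))
      stop("TSE sidecar length does not match stack in ", mpath)
    out$tse <- list(images = stack, te_ms = man$tse$te_ms,
                    sigma = man$tse$sigma)
  }
  if (!is.null(man$afi)) {
    out$afi <- list(s1 = rd(man$afi$s1), s2 = rd(man$afi$s2),
                    geometry = vol_geometry(man$afi$origin_mm,
                                            man$afi$spacing_mm),
                    theta_nominal_deg = man$afi$theta_nominal_deg,
                    tr_ratio = man$afi$tr_ratio)
  }
  out
}

#' Simulate a complete exam and write it to disk
#'
#' Convenience wrapper: phantom, IR series, TSE series and AFI pair from one
#' seed, written via [write_exam()].
#'
#' @param dir Output directory.
#' @param spec A `phantom_spec`.
#' @param gm A `generating_model`.
#' @param seed Integer seed.
#' @param with_afi Simulate the AFI pair (set `FALSE` to emulate exams where
#'   the B1 map was not obtained).
#' @param subject_id,exam_id Identifiers.
#' @param ir_proto,tse_proto,grid,pulses Acquisition models.
#' @return The manifest path, invisibly.
#' @export
simulate_exam <- function(dir, spec = phantom_spec(), gm = generating_model(),
                          seed = 1, with_afi = TRUE, subject_id = 1L,
                          exam_id = 1L, ir_proto = ir_protocol(),
                          tse_proto = tse_protocol(),
                          grid = isochromat_grid(), pulses = pulse_model()) {
  truth <- make_phantom(spec, gm, seed)
  ir <- simulate_ir_series(truth, ir_proto, seed = seed + 1L)
  tse <- simulate_tse_series(truth, tse_proto, grid, pulses, seed = seed + 2L)
  afi <- if (with_afi) simulate_afi_pair(truth, seed = seed + 3L) else NULL
  write_exam(dir, truth, ir, tse, afi, subject_id, exam_id, seed)
}

#' Run the full mapping pipeline on one exam
#'
#' Registration and inversion-recovery T1 fitting; AFI inversion, B1
#' resampling and dictionary T2 matching (skipped with a logged reason when
#' the exam has no AFI data); label erosion and per-tissue medians. Returns
#' maps, the long-format ROI rows and a processing log.
#'
#' @param exam An exam as returned by [read_exam()] (or the directory path).
#' @param fd A `t2_dictionary_fine` for T2 matching (`NULL` skips T2).
#' @param register Run rigid registration of the IR series first.
#' @param drop_ti Indices of IR images to reject before fitting.
#' @param min_pixels Minimum pixels per reported ROI median.
#' @param erode Erode labels by one pixel before summarising.
#' @return A list: `t1_map`, `t2_map`, `b1_slice`, `roi` (data frame with
#'   `exam_id`, `tissue`, `parameter`, `median`, `n_pixels`), `log`.
#' @export
run_pipeline <- function(exam, fd = NULL, register = FALSE,
                         drop_ti = integer(), min_pixels = 10, erode = TRUE) {
  if (is.character(exam)) exam <- read_exam(exam)
  log <- character()
  lm <- exam$labels
  mask <- lm$labels > 0
  ir_proto <- ir_protocol()
  stack <- exam$ir$images
  ti <- exam$ir$ti_s
  if (length(drop_ti)) {
    keep <- setdiff(seq_along(ti), drop_ti)
    stack <- stack[, , keep, drop = FALSE]
    ti <- ti[keep]
    log <- c(log, paste("dropped IR images:", paste(drop_ti, collapse = ",")))
  }
  if (register) {
    reg <- register_series(stack, reference_index = 1)
    stack <- reg$stack
    log <- c(log, "registered IR series")
  }
  t1_map <- fit_t1_map(stack, mask, proto = NULL, ti_s = ti)
  log <- c(log, sprintf("fitted T1 in %d voxels", sum(mask)))

  t2_map <- NULL; b1_slice <- NULL
  if (is.null(exam$afi)) {
    log <- c(log, "no AFI acquired: T2 not estimated")
  } else if (is.null(fd)) {
    log <- c(log, "no dictionary supplied: T2 not estimated")
  } else {
    b1v <- afi_b1_map(exam$afi$s1, exam$afi$s2, exam$afi$tr_ratio,
                      exam$afi$theta_nominal_deg)
    sg <- slice_geometry(spacing_mm = rep(exam$pixel_mm, 2),
                         dims = dim(lm$labels))
    b1_slice <- resample_b1_to_slice(b1v$b1rel, exam$afi$geometry, sg)$b1rel
    b1_slice[is.na(b1_slice)] <- mean(b1_slice, na.rm = TRUE)
    fb <- fd$fine_axes$b1
    b1_slice <- pmin(pmax(b1_slice, min(fb)), max(fb))
    t2_map <- fit_t2_map(exam$tse$images, b1_slice, mask, fd)
    log <- c(log, sprintf("fitted T2 in %d voxels", sum(mask)))
  }

  lm_e <- if (erode) erode_labels(lm) else lm
  roi_t1 <- summarize_roi(t1_map$t1_ms, lm_e, min_pixels,
                          valid = t1_map$qc == 0L)
  roi_t1$parameter <- "T1"
  roi <- roi_t1
  if (!is.null(t2_map)) {
    roi_t2 <- summarize_roi(t2_map$t2_ms, lm_e, min_pixels,
                            valid = t2_map$valid)
    roi_t2$parameter <- "T2"
    roi <- rbind(roi, roi_t2)
  } else {
    roi_t2 <- roi_t1
    roi_t2$median <- NA_real_; roi_t2$n_pixels <- 0L
    roi_t2$parameter <- "T2"
    roi <- rbind(roi, roi_t2)
  }
  roi <- data.frame(exam_id = exam$exam_id, roi[c("tissue", "parameter",
                                                  "median", "n_pixels")])
  list(t1_map = t1_map, t2_map = t2_map, b1_slice = b1_slice, roi = roi,
       log = log)
}
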