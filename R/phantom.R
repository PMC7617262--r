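#' Specification of a synthetic 2D brain phantom
#'
#' Controls the geometry seed-jittered digital phantom used to emulate the
#' single-slice acquisitions: slice shape, age (which sets tissue relaxation
#' times through the generating model), the signal-to-noise ratio of the
#' reference image (no-inversion image for IR, first echo for TSE), optional
#' rigid inter-image motion bounds, and the range of the smooth relative-B1
#' field.
#'
#' @param shape Matrix dimensions `(nrow, ncol)` of the slice.
#' @param pma_weeks Postmenstrual age of the simulated infant, weeks.
#' @param noise_snr Reference-image SNR (Inf for noiseless).
#' @param motion_px_deg Bounds `(pixels, degrees)` for per-image rigid
#'   jitter; `c(0, 0)` disables motion.
#' @param b1_range Range of the smooth relative-B1 field.
#' @param eps_range Range of the smooth inversion-inefficiency field.
#' @param within_tissue_jitter Relative SD-free uniform jitter (+/- fraction)
#'   applied voxelwise to tissue T1/T2 for realism.
#' @param pixel_mm In-plane pixel size, mm.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(160, 160), pma_weeks = 40, noise_snr = 50,
                         motion_px_deg = c(0, 0), b1_range = c(0.65, 1.25),
                         eps_range = c(0.03, 0.12),
                         within_tissue_jitter = 0.01, pixel_mm = 0.8) {
  stopifnot(length(shape) == 2, all(shape >= 64), noise_snr > 0,
            length(b1_range) == 2, b1_range[1] >= 0.2, b1_range[2] <= 1.5,
            b1_range[1] <= b1_range[2], all(motion_px_deg >= 0),
            eps_range[1] >= 0, eps_range[2] < 0.5,
            within_tissue_jitter >= 0, within_tissue_jitter < 0.1)
  structure(list(shape = as.integer(shape), pma_weeks = pma_weeks,
                 noise_snr = noise_snr, motion_px_deg = motion_px_deg,
                 b1_range = b1_range, eps_range = eps_range,
                 within_tissue_jitter = within_tissue_jitter,
                 pixel_mm = pixel_mm),
            class = "phantom_spec")
}

.ellipse_mask <- function(nr, nc, cy, cx, ry, rx, theta_deg = 0) {
  y <- matrix(seq_len(nr), nr, nc) - cy
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  th <- theta_deg * pi / 180
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  (u / rx)^2 + (v / ry)^2 <= 1
}

# smooth in-range field: tilted Gaussian bump rescaled to [lo, hi]
.smooth_field <- function(nr, nc, lo, hi, cy, cx, sigma, tilt = c(0, 0)) {
  if (hi == lo) return(matrix(lo, nr, nc))
  y <- matrix(seq_len(nr), nr, nc)
  x <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  f <- exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2)) +
    tilt[1] * (y - nr / 2) / nr + tilt[2] * (x - nc / 2) / nc
  f <- (f - min(f)) / (max(f) - min(f))
  lo + (hi - lo) * f
}

#' Generate a synthetic brain-like phantom with known truth
#'
#' Builds a 2D label map containing all eight tissues (a cortical ribbon
#' around a white-matter interior, paired deep grey nuclei, brainstem,
#' cerebellar lobes with a midline vermis, and PVFWM caps composited with
#' priority), voxelwise true T1/T2 maps from the generating model at the
#' phantom's age with a small within-tissue jitter, a proton-density-like
#' S0 map, a smooth relative-B1 field and a smooth inversion-inefficiency
#' field. Deterministic given the seed; every tissue is guaranteed at least
#' 50 pixels.
#'
#' @param spec A `phantom_spec`.
#' @param gm A `generating_model`.
#' @param seed Integer seed controlling geometry jitter and voxel jitter.
#' @return A list of class `phantom_truth`: `labels` (a `label_map`),
#'   `t1_ms`, `t2_ms`, `eps`, `s0`, `b1rel` (matrices), `tissue_table`
#'   (per-tissue generating values), `spec`, `seed`, `geometry`
#'   (a `slice_geometry`).
#' @export
make_phantom <- function(spec = phantom_spec(), gm = generating_model(),
                         seed = 1) {
  with_seed(seed, {
    nr <- spec$shape[1]; nc <- spec$shape[2]
    sc <- min(nr, nc) / 160   # geometry designed on a 160 px canvas
    jit <- function(a) stats::runif(1, -a, a) * sc
    cy <- nr / 2 - 6 * sc + jit(2); cx <- nc / 2 + jit(2)
    lab <- matrix(0L, nr, nc)
    tl <- tissue_labels()
    brain <- .ellipse_mask(nr, nc, cy, cx, 64 * sc + jit(2), 56 * sc + jit(2))
    inner <- .ellipse_mask(nr, nc, cy, cx, 56 * sc, 48 * sc)
    lab[brain] <- tl[["cortical_gm"]]
    lab[inner] <- tl[["white_matter"]]
    # deep grey nuclei: basal ganglia lateral pair, thalami near midline
    for (s in c(-1, 1)) {
      lab[.ellipse_mask(nr, nc, cy + 2 * sc, cx + s * 20 * sc + jit(1),
                        10 * sc, 7 * sc, s * 20)] <- tl[["basal_ganglia"]]
      lab[.ellipse_mask(nr, nc, cy + 14 * sc, cx + s * 9 * sc + jit(1),
                        8 * sc, 6 * sc, s * 10)] <- tl[["thalamus"]]
    }
    # infratentorial: brainstem column, cerebellar lobes, midline vermis
    lab[.ellipse_mask(nr, nc, cy + 32 * sc + jit(1), cx, 12 * sc, 7 * sc)] <-
      tl[["brainstem"]]
    for (s in c(-1, 1))
      lab[.ellipse_mask(nr, nc, cy + 46 * sc, cx + s * 24 * sc + jit(1),
                        11 * sc, 14 * sc, -s * 15)] <- tl[["cerebellum"]]
    lab[.ellipse_mask(nr, nc, cy + 48 * sc + jit(1), cx, 9 * sc, 6 * sc)] <-
      tl[["cerebellar_vermis"]]
    # PVFWM caps beside the frontal horns; composited last (priority)
    for (s in c(-1, 1))
      lab[.ellipse_mask(nr, nc, cy - 18 * sc, cx + s * 16 * sc + jit(1),
                        7 * sc, 6 * sc, s * 25)] <- tl[["pvfwm"]]
    counts <- table(factor(lab[lab > 0], levels = tl))
    if (any(counts < 50))
      stop("phantom shape too small: tissues with < 50 px: ",
           paste(names(tl)[counts < 50], collapse = ", "))
    lm <- label_map(lab, tl)

    pars <- tissue_params_all(spec$pma_weeks, gm)
    t1 <- t2 <- s0 <- matrix(0, nr, nc)
    pd <- c(cortical_gm = 0.85, white_matter = 0.78, brainstem = 0.8,
            cerebellum = 0.85, cerebellar_vermis = 0.84, basal_ganglia = 0.86,
            thalamus = 0.86, pvfwm = 0.8)
    j <- spec$within_tissue_jitter
    for (tn in names(tl)) {
      sel <- lab == tl[[tn]]
      n <- sum(sel)
      t1[sel] <- pars$t1_ms[tn] * (1 + stats::runif(n, -j, j))
      t2[sel] <- pars$t2_ms[tn] * (1 + stats::runif(n, -j, j))
      s0[sel] <- pd[[tn]] * (1 + stats::runif(n, -0.02, 0.02))
    }
    b1 <- .smooth_field(nr, nc, spec$b1_range[1], spec$b1_range[2],
                        cy + jit(6), cx + jit(6), 55 * sc, tilt = c(0.15, 0.1))
    eps <- .smooth_field(nr, nc, spec$eps_range[1], spec$eps_range[2],
                         cy - 20 * sc + jit(6), cx + jit(6), 70 * sc,
                         tilt = c(-0.1, 0.12))
    structure(list(labels = lm, t1_ms = t1, t2_ms = t2, eps = eps, s0 = s0,
                   b1rel = b1,
                   tissue_table = data.frame(tissue = names(tl),
                                             t1_ms = unname(pars$t1_ms[names(tl)]),
                                             t2_ms = unname(pars$t2_ms[names(tl)])),
                   spec = spec, seed = seed,
                   geometry = slice_geometry(spacing_mm = rep(spec$pixel_mm, 2),
                                             dims = spec$shape)),
              class = "phantom_truth")
  })
}

# generating-line values for every tissue at one age, as named vectors
tissue_params_all <- function(pma_weeks, gm = generating_model()) {
  tl <- gm$tissue_lines
  t1 <- stats::setNames(tl$t1_40wk_ms + tl$d1_ms_per_week * (pma_weeks - 40),
                        tl$tissue)
  t2 <- stats::setNames(tl$t2_40wk_ms + tl$d2_ms_per_week * (pma_weeks - 40),
                        tl$tissue)
  list(t1_ms = t1, t2_ms = t2)
}
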