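#' Simulate an inversion-recovery image series from a phantom
#'
#' Evaluates the signed inversion-recovery signal voxelwise (including the
#' no-inversion image), scales by the phantom's S0 map, optionally applies a
#' small random rigid motion to each image, and adds Rician noise at the
#' SNR of the no-inversion image defined over the brain.
#'
#' @param truth A `phantom_truth`.
#' @param proto An `ir_protocol`.
#' @param seed Seed for motion and noise.
#' @return A list: `images` (array `[nr, nc, n_ti]` of magnitudes), `ti_s`,
#'   `sigma` (noise SD), `motion` (data frame of applied transforms),
#'   `truth`.
#' @export
simulate_ir_series <- function(truth, proto = ir_protocol(), seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  ti <- ir_ti_full(proto)
  nr <- nrow(truth$t1_ms); nc <- ncol(truth$t1_ms)
  brain <- truth$labels$labels > 0
  sref <- stats::median(truth$s0[brain])
  sigma <- if (is.finite(spec$noise_snr)) sref / spec$noise_snr else 0
  with_seed(seed, {
    motion <- data.frame(dx = numeric(length(ti)), dy = 0, theta_deg = 0)
    if (any(spec$motion_px_deg > 0)) {
      motion$dx <- stats::runif(length(ti), -1, 1) * spec$motion_px_deg[1]
      motion$dy <- stats::runif(length(ti), -1, 1) * spec$motion_px_deg[1]
      motion$theta_deg <- stats::runif(length(ti), -1, 1) * spec$motion_px_deg[2]
      motion[1, ] <- 0  # reference image stays put
    }
    imgs <- array(0, c(nr, nc, length(ti)))
    for (k in seq_along(ti)) {
      signed <- matrix(0, nr, nc)
      signed[brain] <- truth$s0[brain] *
        (if (is.infinite(ti[k])) 1 else
           1 - 2 * (1 - truth$eps[brain]) * exp(-ti[k] / (truth$t1_ms[brain] / 1000)))
      if (any(abs(unlist(motion[k, ])) > 0))
        signed <- apply_rigid(signed, motion$dx[k], motion$dy[k],
                              motion$theta_deg[k], fill = 0)
      imgs[, , k] <- add_rician(signed, sigma)
    }
    list(images = imgs, ti_s = ti, sigma = sigma, motion = motion,
         truth = truth)
  })
}

# echo-amplitude lookup tables per tissue: atoms on a (t2 x b1) local grid,
# shared composite operators per b1 node
.tissue_echo_tables <- function(truth, proto, grid, pulses, n_b1 = 16) {
  b1r <- range(truth$b1rel)
  if (diff(b1r) < 1e-12) {
    # constant field: node 1 sits exactly on it, so interpolation is exact
    b1_nodes <- b1r[1] + c(0, 1e-6)
    n_b1 <- 2L
  } else {
    pad <- max(0.01, diff(b1r) * 0.05)
    b1_nodes <- seq(max(0.05, b1r[1] - pad), min(2, b1r[2] + pad),
                    length.out = n_b1)
  }
  tt <- truth$tissue_table
  j <- truth$spec$within_tissue_jitter
  t2f <- c(1 - 1.5 * max(j, 0.005), 1, 1 + 1.5 * max(j, 0.005))
  esp_s <- proto$echo_spacing_ms / 1000
  tabs <- vector("list", nrow(tt))
  names(tabs) <- tt$tissue
  for (tn in tt$tissue)
    tabs[[tn]] <- array(NA_real_, c(3, n_b1, length(proto$echo_indices)))
  for (ib in seq_len(n_b1)) {
    ops <- .train_operators(proto, grid, pulses, b1_nodes[ib])
    for (r in seq_len(nrow(tt))) {
      for (m in 1:3) {
        tr <- .run_train(ops, tt$t1_ms[r] / 1000, tt$t2_ms[r] * t2f[m] / 1000,
                         proto$etl, esp_s)
        tabs[[tt$tissue[r]]][m, ib, ] <- tr[proto$echo_indices]
      }
    }
  }
  list(tables = tabs, b1_nodes = b1_nodes, t2_factors = t2f)
}

#' Simulate a multi-TE TSE image series from a phantom
#'
#' Voxel signals are Bloch-simulated echo-centre amplitudes for the voxel's
#' (T1, T2, B1rel), scaled by the S0 map. For tractability the simulation is
#' run per tissue on a small local (T2, B1) grid and interpolated to each
#' voxel's jittered T2 and B1 value, then Rician noise is added at the SNR
#' of the first-echo image over the brain.
#'
#' @param truth A `phantom_truth`.
#' @param proto A `tse_protocol`.
#' @param grid An `isochromat_grid`.
#' @param pulses A `pulse_model`.
#' @param seed Seed for noise and motion.
#' @return A list: `images` (array `[nr, nc, n_echo]`), `te_ms`, `sigma`,
#'   `motion`, `truth`.
#' @export
simulate_tse_series <- function(truth, proto = tse_protocol(),
                                grid = isochromat_grid(),
                                pulses = pulse_model(), seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  nr <- nrow(truth$t2_ms); nc <- ncol(truth$t2_ms)
  ne <- length(proto$echo_indices)
  lut <- .tissue_echo_tables(truth, proto, grid, pulses)
  lab <- truth$labels$labels
  tl <- truth$labels$tissue_names
  clean <- array(0, c(nr, nc, ne))
  for (tn in names(tl)) {
    sel <- which(lab == tl[[tn]])
    if (!length(sel)) next
    row <- truth$tissue_table[truth$tissue_table$tissue == tn, ]
    t2rel <- truth$t2_ms[sel] / row$t2_ms
    w2 <- .interp_weights(lut$t2_factors, pmin(pmax(t2rel, min(lut$t2_factors)),
                                               max(lut$t2_factors)))
    wb <- .interp_weights(lut$b1_nodes, pmin(pmax(truth$b1rel[sel],
                                                  min(lut$b1_nodes)),
                                             max(lut$b1_nodes)))
    tab <- lut$tables[[tn]]
    for (e in seq_len(ne)) {
      v <- (1 - w2$w) * ((1 - wb$w) * tab[cbind(w2$i, wb$i, e)] +
                           wb$w * tab[cbind(w2$i, wb$i + 1, e)]) +
        w2$w * ((1 - wb$w) * tab[cbind(w2$i + 1, wb$i, e)] +
                  wb$w * tab[cbind(w2$i + 1, wb$i + 1, e)])
      pl <- clean[, , e]
      pl[sel] <- v * truth$s0[sel]
      clean[, , e] <- pl
    }
  }
  brain <- lab > 0
  sref <- stats::median(clean[, , 1][brain])
  sigma <- if (is.finite(spec$noise_snr)) sref / spec$noise_snr else 0
  with_seed(seed, {
    motion <- data.frame(dx = numeric(ne), dy = 0, theta_deg = 0)
    if (any(spec$motion_px_deg > 0)) {
      motion$dx <- stats::runif(ne, -1, 1) * spec$motion_px_deg[1]
      motion$dy <- stats::runif(ne, -1, 1) * spec$motion_px_deg[1]
      motion$theta_deg <- stats::runif(ne, -1, 1) * spec$motion_px_deg[2]
      motion[1, ] <- 0
    }
    imgs <- array(0, c(nr, nc, ne))
    for (e in seq_len(ne)) {
      pl <- clean[, , e]
      if (any(abs(unlist(motion[e, ])) > 0))
        pl <- apply_rigid(pl, motion$dx[e], motion$dy[e], motion$theta_deg[e],
                          fill = 0)
      imgs[, , e] <- add_rician(pl, sigma)
    }
    list(images = imgs, te_ms = proto$te_centers_ms, sigma = sigma,
         motion = motion, truth = truth)
  })
}

#' Simulate a dual-TR AFI volume pair from the phantom's B1 field
#'
#' The phantom's 2D relative-B1 field is block-averaged to the coarser AFI
#' resolution and replicated through-slab into a thin axis-aligned 3D
#' volume; the two steady-state images follow the short-TR ideal-spoiling
#' ratio model used by the estimator, so noiseless simulation inverts
#' exactly.
#'
#' @param truth A `phantom_truth`.
#' @param theta_nominal_deg Nominal flip angle, degrees.
#' @param tr_ratio TR2 / TR1.
#' @param afi_spacing_mm AFI voxel spacing `(x, y, z)`, mm.
#' @param n_slabs Number of replicated slices in z.
#' @param seed Seed for noise.
#' @return A list: `s1`, `s2` (3D arrays), `geometry` (a `vol_geometry`),
#'   `b1rel_true` (3D array), `theta_nominal_deg`, `tr_ratio`, `sigma`.
#' @export
simulate_afi_pair <- function(truth, theta_nominal_deg = 60, tr_ratio = 5,
                              afi_spacing_mm = c(2.2, 2.2, 3), n_slabs = 3,
                              seed = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  f <- afi_spacing_mm[1] / spec$pixel_mm
  # resample the smooth field at the coarse grid by bilinear interpolation
  nr <- nrow(truth$b1rel); nc <- ncol(truth$b1rel)
  nrv <- floor(nr / f); ncv <- floor(nc / f)
  rr <- (seq_len(nrv) - 0.5) * f + 0.5
  cc <- (seq_len(ncv) - 0.5) * f + 0.5
  b1c <- bilinear_sample(truth$b1rel, matrix(rr, nrv, ncv),
                         matrix(cc, nrv, ncv, byrow = TRUE), fill = NA_real_)
  b1c[is.na(b1c)] <- mean(truth$b1rel)
  # volume axis 1 follows world x (slice columns), axis 2 world y (rows)
  b1v <- array(rep(t(b1c), n_slabs), c(ncv, nrv, n_slabs))
  theta <- b1v * theta_nominal_deg
  s1 <- sin(theta * pi / 180)
  s2 <- s1 * afi_forward_ratio(theta, tr_ratio)
  sigma <- if (is.finite(spec$noise_snr)) mean(s1) / spec$noise_snr else 0
  if (sigma > 0) {
    s1 <- with_seed(seed, add_rician(s1, sigma))
    s2 <- with_seed(seed + 1L, add_rician(s2, sigma))
  }
  # origin: coarse voxel (1,1,1) centre in the slice's world frame, with the
  # slab centred on the slice plane (z = 0)
  geom <- vol_geometry(
    origin_mm = c((cc[1] - 1) * spec$pixel_mm, (rr[1] - 1) * spec$pixel_mm,
                  -afi_spacing_mm[3] * (n_slabs - 1) / 2),
    spacing_mm = c(afi_spacing_mm[1], afi_spacing_mm[2], afi_spacing_mm[3]))
  list(s1 = s1, s2 = s2, geometry = geom, b1rel_true = b1v,
       theta_nominal_deg = theta_nominal_deg, tr_ratio = tr_ratio,
       sigma = sigma)
}

#' Measure image SNR from a background region
#'
#' Estimates the noise SD from a signal-free background region of a
#' magnitude image (Rician background has mean `sigma * sqrt(pi / 2)`), and
#' the SNR as the brain median divided by that estimate.
#'
#' @param img Magnitude image.
#' @param brain Logical matrix marking brain pixels.
#' @param background Logical matrix marking signal-free pixels.
#' @return A list with `sigma_hat` and `snr_hat`.
#' @export
measure_background_snr <- function(img, brain, background) {
  sigma_hat <- mean(img[background]) / sqrt(pi / 2)
  list(sigma_hat = sigma_hat,
       snr_hat = stats::median(img[brain]) / sigma_hat)
}
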