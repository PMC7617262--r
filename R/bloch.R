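#' Isochromat grid for voxel-integrated Bloch simulation
#'
#' Isochromats tile a voxel of `extent_readout_mm` along the readout axis and
#' `extent_slice_mm` through-slice, symmetric about the voxel centre. No
#' gradient is applied along the readout axis in this model, so readout
#' positions contribute a pure multiplicity; the slice axis carries the
#' slice-selection and crusher gradient phase.
#'
#' @param n_readout Number of isochromats along readout.
#' @param n_slice Number of isochromats through-slice.
#' @param extent_readout_mm Simulated extent along readout, mm.
#' @param extent_slice_mm Simulated extent through-slice, mm.
#' @return An object of class `isochromat_grid`.
#' @export
isochromat_grid <- function(n_readout = 51, n_slice = 501,
                            extent_readout_mm = 1, extent_slice_mm = 4) {
  stopifnot(n_readout >= 1, n_slice >= 3, extent_readout_mm > 0, extent_slice_mm > 0)
  n_slice <- as.integer(n_slice)
  n_readout <- as.integer(n_readout)
  # midpoint positions: uniform spacing L/n, symmetric about 0
  z <- (seq_len(n_slice) - 0.5) / n_slice - 0.5
  structure(list(n_readout = n_readout, n_slice = n_slice,
                 extent_readout_mm = extent_readout_mm,
                 extent_slice_mm = extent_slice_mm,
                 z_mm = z * extent_slice_mm,
                 n_isochromats = n_readout * n_slice),
            class = "isochromat_grid")
}

#' Slice-selective RF pulse model
#'
#' Shaped pulses are Hamming-windowed sinc pulses discretized into hard-pulse
#' samples; the slice-selection gradient enters as an interleaved rotation
#' about z whose total phase across the slice thickness equals 2*pi times the
#' time-bandwidth product. `shape = "hard"` selects ideal non-selective
#' delta pulses (used for closed-form CPMG limits). Crusher gradients are
#' modelled as an instantaneous linear phase of `crusher_cycles` cycles
#' across the simulated through-slice extent on each side of every
#' refocusing pulse. Because practical crushers dephase spins by many cycles
#' within each grid position, every position additionally carries
#' `crusher_phase_samples` uniformly spread intra-voxel phase offsets (the
#' strong-crusher limit): coherence pathways whose net crusher count is not
#' a multiple of that sample count cancel exactly, instead of relying on
#' imperfect cancellation across the discrete profile grid.
#'
#' Pulses are applied as instantaneous composite rotations: relaxation is
#' accounted for over the full free-precession intervals (which preserve the
#' exact echo timing), not within the RF waveform itself.
#'
#' @param shape `"hsinc"` (Hamming-windowed sinc) or `"hard"`.
#' @param tbw Time-bandwidth product of the shaped pulse.
#' @param n_samples Hard-pulse samples per shaped pulse.
#' @param refocus_phase_deg RF phase of refocusing pulses relative to
#'   excitation (90 gives the CPMG condition).
#' @param crusher_cycles Crusher phase cycles across the through-slice extent.
#' @param crusher_phase_samples Intra-voxel crusher phase offsets per grid
#'   position (strong-crusher limit; 1 disables the sub-ensemble).
#' @param duration_ms Pulse duration, metadata only (the hard-pulse
#'   discretization of an instantaneous composite rotation does not depend
#'   on it).
#' @return An object of class `pulse_model`.
#' @export
pulse_model <- function(shape = c("hsinc", "hard"), tbw = 4, n_samples = 250,
                        refocus_phase_deg = 90, crusher_cycles = 4,
                        crusher_phase_samples = 8, duration_ms = 2.56) {
  shape <- match.arg(shape)
  stopifnot(tbw > 0, n_samples >= 10, crusher_cycles >= 2,
            crusher_phase_samples >= 1)
  structure(list(shape = shape, tbw = tbw, n_samples = as.integer(n_samples),
                 refocus_phase_deg = refocus_phase_deg,
                 crusher_cycles = crusher_cycles,
                 crusher_phase_samples = as.integer(crusher_phase_samples),
                 duration_ms = duration_ms),
            class = "pulse_model")
}

# Hamming-windowed sinc envelope sampled at n midpoints of [-1/2, 1/2],
# scaled so the sample flip angles sum to the nominal flip.
.rf_envelope <- function(tbw, n) {
  t <- (seq_len(n) - 0.5) / n - 0.5
  x <- tbw * t
  env <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x)) * (0.54 + 0.46 * cos(2 * pi * t))
  env / sum(env)
}

# Composite rotation of one shaped slice-selective pulse for every slice
# isochromat, as nine vectors (row-major 3x3 entries). Interleaves constant
# RF kicks with per-isochromat gradient z-rotations (symmetric splitting).
# `rephase` appends a z-rotation of minus half the accumulated gradient
# phase (the slice-refocusing lobe after excitation).
.composite_rotation <- function(pulses, grid, flip_deg, phase_deg, b1rel,
                                slice_thickness_mm, rephase = FALSE) {
  ns <- grid$n_slice
  if (pulses$shape == "hard") {
    a <- flip_deg * b1rel * pi / 180
    ph <- phase_deg * pi / 180
    R <- .axis_rotation(a, ph)
    return(lapply(as.vector(t(R)), rep, times = ns))
  }
  env <- .rf_envelope(pulses$tbw, pulses$n_samples)
  flips <- flip_deg * b1rel * pi / 180 * env
  ph <- phase_deg * pi / 180
  # per-substep gradient phase: total 2*pi*tbw*z/dz across the pulse
  gtot <- 2 * pi * pulses$tbw * grid$z_mm / slice_thickness_mm
  g <- gtot / pulses$n_samples
  cg <- cos(g); sg <- sin(g)
  ch <- cos(g / 2); sh <- sin(g / 2)
  # state: rows of the accumulated rotation, 9 vectors length ns
  A <- list(rep(1, ns), rep(0, ns), rep(0, ns),
            rep(0, ns), rep(1, ns), rep(0, ns),
            rep(0, ns), rep(0, ns), rep(1, ns))
  rot_z <- function(A, c, s) {
    a1 <- c * A[[1]] - s * A[[4]]; a2 <- c * A[[2]] - s * A[[5]]; a3 <- c * A[[3]] - s * A[[6]]
    A[[4]] <- s * A[[1]] + c * A[[4]]; A[[5]] <- s * A[[2]] + c * A[[5]]; A[[6]] <- s * A[[3]] + c * A[[6]]
    A[[1]] <- a1; A[[2]] <- a2; A[[3]] <- a3
    A
  }
  rot_const <- function(A, R) {
    B <- A
    for (i in 0:2) for (j in 1:3)
      B[[3 * i + j]] <- R[i + 1, 1] * A[[j]] + R[i + 1, 2] * A[[3 + j]] + R[i + 1, 3] * A[[6 + j]]
    B
  }
  A <- rot_z(A, ch, sh)
  for (k in seq_along(flips)) {
    A <- rot_const(A, .axis_rotation(flips[k], ph))
    if (k < length(flips)) A <- rot_z(A, cg, sg)
  }
  A <- rot_z(A, ch, sh)
  if (rephase) {
    cr <- cos(-gtot / 2); sr <- sin(-gtot / 2)
    A <- rot_z(A, cr, sr)
  }
  A
}

# Rotation by angle a about an axis in the transverse plane at azimuth ph.
.axis_rotation <- function(a, ph) {
  ca <- cos(a); sa <- sin(a); cp <- cos(ph); sp <- sin(ph)
  matrix(c(
    cp * cp + sp * sp * ca, cp * sp * (1 - ca),      sp * sa,
    cp * sp * (1 - ca),     sp * sp + cp * cp * ca, -cp * sa,
    -sp * sa,               cp * sa,                 ca), 3, 3, byrow = TRUE)
}

# Precompute the per-b1 operators reused across (T1, T2) pairs. The state
# vectors tile the profile grid `crusher_phase_samples` times, each copy
# with a different intra-voxel crusher phase offset.
.train_operators <- function(proto, grid, pulses, b1rel) {
  exc <- .composite_rotation(pulses, grid, 90, 0, b1rel,
                             proto$slice_thickness_mm, rephase = TRUE)
  ref <- .composite_rotation(pulses, grid, proto$refocus_deg,
                             pulses$refocus_phase_deg, b1rel,
                             proto$slice_thickness_mm)
  k <- pulses$crusher_phase_samples
  crush <- rep(2 * pi * pulses$crusher_cycles * grid$z_mm /
                 grid$extent_slice_mm, times = k) +
    rep(2 * pi * (seq_len(k) - 1) / k, each = grid$n_slice)
  tile <- function(v) rep(v, times = k)
  list(
    # magnetization just after excitation of unit M0 (third column of exc)
    m0 = list(x = tile(exc[[3]]), y = tile(exc[[6]]), z = tile(exc[[9]])),
    ref = lapply(ref, tile), cc = cos(crush), cs = sin(crush),
    n_state = grid$n_slice * k)
}

# Echo train from precomputed operators; returns etl magnitudes.
.run_train <- function(ops, t1_s, t2_s, etl, esp_s) {
  n_state <- ops$n_state
  e1 <- exp(-esp_s / 2 / t1_s); e2 <- exp(-esp_s / 2 / t2_s)
  r <- ops$ref; cc <- ops$cc; cs <- ops$cs
  mx <- ops$m0$x; my <- ops$m0$y; mz <- ops$m0$z
  out <- numeric(etl)
  for (k in seq_len(etl)) {
    mx <- mx * e2; my <- my * e2; mz <- mz * e1 + (1 - e1)
    tx <- cc * mx - cs * my; my <- cs * mx + cc * my; mx <- tx
    nx <- r[[1]] * mx + r[[2]] * my + r[[3]] * mz
    ny <- r[[4]] * mx + r[[5]] * my + r[[6]] * mz
    nz <- r[[7]] * mx + r[[8]] * my + r[[9]] * mz
    tx <- cc * nx - cs * ny; ny <- cs * nx + cc * ny; nx <- tx
    mx <- nx * e2; my <- ny * e2; mz <- nz * e1 + (1 - e1)
    out[k] <- sqrt(sum(mx)^2 + sum(my)^2) / n_state
  }
  out
}

#' Simulate one slice-selective TSE echo train
#'
#' Evolves the isochromat ensemble through excitation, the crusher-flanked
#' refocusing train and free relaxation, integrating transverse
#' magnetization over the voxel and returning the magnitude at each echo
#' centre. Output is normalized so that unit equilibrium magnetization with
#' an ideal non-selective 90 degree excitation gives amplitude 1 in the
#' no-decay limit.
#'
#' @param t1_s Longitudinal relaxation time, seconds.
#' @param t2_s Transverse relaxation time, seconds.
#' @param b1rel Relative transmit field scaling every flip angle.
#' @param proto A `tse_protocol`.
#' @param grid An `isochromat_grid`.
#' @param pulses A `pulse_model`.
#' @return Numeric vector of `proto$etl` echo magnitudes.
#' @export
simulate_echo_train <- function(t1_s, t2_s, b1rel,
                                proto = tse_protocol(),
                                grid = isochromat_grid(),
                                pulses = pulse_model()) {
  if (!is.finite(t1_s) || !is.finite(t2_s) || t1_s <= 0 || t2_s <= 0)
    stop("relaxation times must be positive and finite")
  stopifnot(b1rel >= 0, b1rel <= 2)
  ops <- .train_operators(proto, grid, pulses, b1rel)
  .run_train(ops, t1_s, t2_s, proto$etl, proto$echo_spacing_ms / 1000)
}

#' Extract the k-space-centre echoes from a train
#'
#' @param train Echo magnitudes of length `proto$etl`.
#' @param proto A `tse_protocol`.
#' @return The entries at `proto$echo_indices`, order preserved.
#' @export
extract_center_echoes <- function(train, proto = tse_protocol()) {
  if (length(train) != proto$etl)
    stop("train length (", length(train), ") does not match protocol ETL (",
         proto$etl, ")")
  train[proto$echo_indices]
}
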