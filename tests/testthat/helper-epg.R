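# Extended-phase-graph oracle for the TSE echo train.
#
# Independent check of the isochromat Bloch simulator: per slice position the
# composite pulse rotation (same discretized slice profile as the simulator)
# is applied to configuration states F_k / Z_k; crushers are ideal unit
# shifts of the transverse configuration order; relaxation acts on the
# states; the echo is the voxel sum of the k = 0 transverse configuration.
# The formalism (configuration-state algebra) shares nothing with the
# isochromat ensemble evolution beyond the pulse profile itself.

# complex-basis coefficients of a 3x3 rotation acting on (M+, M-, Mz)
.epg_rot_coeffs <- function(R9, i) {
  R <- matrix(unlist(lapply(R9, `[`, i)), 3, 3, byrow = TRUE)
  list(a = complex(real = (R[1, 1] + R[2, 2]) / 2,
                   imaginary = (R[2, 1] - R[1, 2]) / 2),
       b = complex(real = (R[1, 1] - R[2, 2]) / 2,
                   imaginary = (R[2, 1] + R[1, 2]) / 2),
       cc = complex(real = R[1, 3], imaginary = R[2, 3]),
       u = complex(real = R[3, 1], imaginary = -R[3, 2]) / 2,
       w = R[3, 3])
}

epg_echo_train <- function(t1_s, t2_s, b1rel, proto = tse_protocol(),
                           grid = isochromat_grid(), pulses = pulse_model()) {
  exc <- neorelax:::.composite_rotation(pulses, grid, 90, 0, b1rel,
                                        proto$slice_thickness_mm,
                                        rephase = TRUE)
  ref <- neorelax:::.composite_rotation(pulses, grid, proto$refocus_deg,
                                        pulses$refocus_phase_deg, b1rel,
                                        proto$slice_thickness_mm)
  etl <- proto$etl
  esp <- proto$echo_spacing_ms / 1000
  e1 <- exp(-esp / 2 / t1_s); e2 <- exp(-esp / 2 / t2_s)
  K <- 2 * etl + 2          # max reachable configuration order
  nk <- 2 * K + 1
  k0 <- K + 1               # index of order zero
  ns <- grid$n_slice
  out <- matrix(complex(real = 0), etl, ns)
  for (i in seq_len(ns)) {
    Fk <- complex(length.out = nk)   # transverse configurations
    Zk <- complex(length.out = nk)   # longitudinal configurations
    m0 <- c(exc[[3]][i], exc[[6]][i], exc[[9]][i])
    Fk[k0] <- complex(real = m0[1], imaginary = m0[2])
    Zk[k0] <- m0[3]
    q <- .epg_rot_coeffs(ref, i)
    shift <- function(F) c(0 + 0i, F[-nk])   # order k -> k + 1
    for (e in seq_len(etl)) {
      Fk <- Fk * e2
      Zk <- Zk * e1; Zk[k0] <- Zk[k0] + (1 - e1)
      Fk <- shift(Fk)
      Fmc <- Conj(rev(Fk))                  # coefficients of M- = conj(M+)
      Fn <- q$a * Fk + q$b * Fmc + q$cc * Zk
      Zn <- q$u * Fk + Conj(q$u) * Fmc + q$w * Zk
      Fk <- Fn; Zk <- Zn
      Fk <- shift(Fk)
      Fk <- Fk * e2
      Zk <- Zk * e1; Zk[k0] <- Zk[k0] + (1 - e1)
      out[e, i] <- Fk[k0]
    }
  }
  Mod(rowSums(out)) / ns
}
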