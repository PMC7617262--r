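test_that("tissue generating lines evaluate the linear age model", {
  p <- tissue_params("white_matter", 40)
  expect_equal(p$t1_ms, 2933)
  expect_equal(p$t2_ms, 119)
  expect_equal(tissue_params("cerebellum", 45)$t1_ms, 2653 - 43 * 5)
  gm0 <- generating_model(tissue_lines = {
    tl <- reference_tissue_lines(); tl$d1_ms_per_week <- 0; tl
  })
  expect_equal(tissue_params("thalamus", 36, gm0)$t1_ms,
               tissue_params("thalamus", 50, gm0)$t1_ms)
  expect_warning(tissue_params("white_matter", 60), "extrapolat")
  expect_error(tissue_params("liver", 40), "unknown tissue")
  # T1 > T2 at all simulated ages, every tissue
  for (pma in c(33, 40, 53)) {
    pp <- suppressWarnings(neorelax:::tissue_params_all(pma))
    expect_true(all(pp$t1_ms > pp$t2_ms))
  }
})

test_that("phantoms are deterministic and contain every tissue", {
  spec <- phantom_spec()
  t1 <- make_phantom(spec, seed = 9)
  t2 <- make_phantom(spec, seed = 9)
  expect_identical(t1$t1_ms, t2$t1_ms)
  expect_identical(t1$labels$labels, t2$labels$labels)
  counts <- table(factor(t1$labels$labels[t1$labels$labels > 0],
                         levels = tissue_labels()))
  expect_true(all(counts >= 50))
  expect_false(identical(make_phantom(spec, seed = 10)$labels$labels,
                         t1$labels$labels))
})

test_that("the B1 field is smooth and in range", {
  truth <- make_phantom(phantom_spec(), seed = 12)
  expect_true(all(truth$b1rel >= 0.65 - 1e-9 & truth$b1rel <= 1.25 + 1e-9))
  gx <- abs(diff(truth$b1rel))            # per-pixel gradient, both axes
  gy <- abs(t(diff(t(truth$b1rel))))
  expect_lt(max(gx, gy), 0.02)
})

test_that("IR simulation obeys the signal equation voxelwise", {
  spec <- phantom_spec(shape = c(96, 96), noise_snr = Inf,
                       eps_range = c(0.2, 0.2), within_tissue_jitter = 0)
  truth <- make_phantom(spec, seed = 3)
  ir <- simulate_ir_series(truth, seed = 4)
  mask <- truth$labels$labels > 0
  # no-inversion image is S0 regardless of eps
  noinv <- ir$images[, , 8]
  expect_lt(max(abs(noinv[mask] - truth$s0[mask])), 1e-12)
  # eps = 0.2 at ti -> 0 gives |1 - 2 * 0.8| = 0.6 of S0
  expect_equal(ir_signal(truth$s0[mask], truth$t1_ms[mask], 0.2, 0),
               -0.6 * truth$s0[mask])
  # at each tissue's null point the noiseless signal vanishes
  wm <- truth$labels$labels == tissue_labels()[["white_matter"]]
  t1wm <- truth$tissue_table$t1_ms[truth$tissue_table$tissue == "white_matter"]
  ti_null <- t1wm / 1000 * log(2 * (1 - 0.2))
  s_null <- abs(ir_signal(truth$s0[wm], truth$t1_ms[wm], truth$eps[wm], ti_null))
  expect_lt(stats::median(s_null), 3 * stats::median(truth$s0[wm]) / 50)
})

test_that("null-point images drown in the noise floor at finite SNR", {
  spec <- phantom_spec(shape = c(96, 96), noise_snr = 50,
                       eps_range = c(0.05, 0.05), within_tissue_jitter = 0)
  truth <- make_phantom(spec, seed = 3)
  t1wm <- truth$tissue_table$t1_ms[truth$tissue_table$tissue == "white_matter"]
  ti_null <- t1wm / 1000 * log(2 * 0.95)
  proto <- ir_protocol(ti_s = sort(c(ti_null, 1, 4)))
  ir <- simulate_ir_series(truth, proto, seed = 4)
  wm <- truth$labels$labels == tissue_labels()[["white_matter"]]
  k <- which(abs(ir$ti_s - ti_null) < 1e-9)
  expect_lt(mean(ir$images[, , k][wm]), 3 * ir$sigma * sqrt(pi / 2))
})

test_that("TSE simulation reduces to exponential decay in the CPMG limit", {
  spec <- phantom_spec(shape = c(96, 96), noise_snr = Inf, b1_range = c(1, 1),
                       within_tissue_jitter = 0)
  truth <- make_phantom(spec, seed = 2)
  tse <- simulate_tse_series(truth, grid = isochromat_grid(n_slice = 51),
                             pulses = pulse_model(shape = "hard"), seed = 1)
  proto <- tse_protocol()
  te_ms <- proto$echo_indices * proto$echo_spacing_ms
  mask <- truth$labels$labels > 0
  for (e in 1:3) {
    expct <- truth$s0 * exp(-te_ms[e] / truth$t2_ms)
    expect_lt(max(abs(tse$images[, , e][mask] - expct[mask])), 1e-6)
  }
})

test_that("simulated image SNR matches the requested level", {
  spec <- phantom_spec(shape = c(120, 120), noise_snr = 40)
  truth <- make_phantom(spec, seed = 13)
  ir <- simulate_ir_series(truth, seed = 14)
  brain <- truth$labels$labels > 0
  background <- !brain & row(truth$s0) > 100         # signal-free corner rows
  m <- measure_background_snr(ir$images[, , 8], brain, background)
  expect_lt(abs(m$snr_hat - 40) / 40, 0.1)
})

test_that("AFI simulation inverts exactly without noise", {
  truth <- make_phantom(phantom_spec(shape = c(96, 96), noise_snr = Inf),
                        seed = 6)
  afi <- simulate_afi_pair(truth, seed = 7)
  b1 <- afi_b1_map(afi$s1, afi$s2, afi$tr_ratio, afi$theta_nominal_deg)
  expect_lt(max(abs(b1$b1rel - afi$b1rel_true)), 1e-6)
  # a b1rel = 1 voxel sees exactly the nominal 60 degrees
  th <- afi_flip_angle(afi$s1, afi$s2, afi$tr_ratio)
  expect_lt(max(abs(th$theta_deg - afi$b1rel_true * 60)), 1e-6)
})

test_that("noisy AFI fields match the error-propagation prediction", {
  # first-order propagation at theta = b1 * 60 deg, n = 5:
  # sigma_r = r * sigma * sqrt(1/s1^2 + 1/s2^2), |dtheta/dr| = (n^2-1) /
  # ((n-r)^2 sin(theta)); at SNR 50 this predicts an RMSE of ~0.033 in
  # relative B1, so the field must land near it and not above 0.045
  truth <- make_phantom(phantom_spec(shape = c(96, 96), noise_snr = 50),
                        seed = 6)
  afi <- simulate_afi_pair(truth, seed = 8)
  b1 <- afi_b1_map(afi$s1, afi$s2, afi$tr_ratio, afi$theta_nominal_deg)
  ok <- b1$valid & !b1$clipped
  rmse <- sqrt(mean((b1$b1rel[ok] - afi$b1rel_true[ok])^2))
  expect_lt(rmse, 0.045)
  expect_gt(rmse, 0.02)
})

test_that("motion jitter is recorded in the series truth", {
  spec <- phantom_spec(shape = c(96, 96), noise_snr = Inf,
                       motion_px_deg = c(2, 1))
  truth <- make_phantom(spec, seed = 15)
  ir <- simulate_ir_series(truth, seed = 16)
  expect_identical(nrow(ir$motion), 8L)
  expect_true(all(unlist(ir$motion[1, ]) == 0))      # reference image fixed
  expect_true(any(abs(ir$motion$dx[-1]) > 0))
  expect_true(all(abs(ir$motion$dx) <= 2 & abs(ir$motion$theta_deg) <= 1))
  # determinism of the whole simulated dataset
  ir2 <- simulate_ir_series(truth, seed = 16)
  expect_identical(ir$images, ir2$images)
})
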