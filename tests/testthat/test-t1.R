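test_that("inversion-recovery signal model has the right fixed points", {
  expect_equal(ir_signal(1, 2600, 0, Inf), 1)       # full recovery
  expect_equal(ir_signal(1, 2600, 0, 2.6 * log(2)), 0)  # null point
  expect_equal(ir_signal(1, 1234, 0.5, 0), 0)       # 2*(1-eps) cancels
  expect_equal(ir_signal(1, 2933, 0, 0.5), -0.6865, tolerance = 1e-4)
  expect_equal(ir_signal(1, 2000, 0.2, 0), -0.6)    # 1 - 2*0.8
})

test_that("noiseless voxel fits recover the generating parameters", {
  proto <- ir_protocol()
  ti <- ir_ti_full(proto)
  for (par in list(c(1, 2600, 0.05), c(0.8, 1500, 0.2), c(1.2, 3200, 0.01))) {
    y <- abs(ir_signal(par[1], par[2], par[3], ti))
    f <- fit_t1_voxel(y, proto)
    expect_true(f$valid && !f$boundary_active)
    expect_equal(f$s0, par[1], tolerance = 1e-3)
    expect_equal(f$t1_ms, par[2], tolerance = 1e-3)
    expect_equal(f$eps, par[3], tolerance = 1e-3)
  }
})

test_that("degenerate voxels are flagged rather than fitted", {
  proto <- ir_protocol()
  ti <- ir_ti_full(proto)
  expect_false(fit_t1_voxel(rep(0, 8), proto)$valid)
  expect_false(fit_t1_voxel(c(rep(NA, 5), 1, 1, 1), proto)$valid)
  # constant signals carry no inversion effect: the fit lands on a
  # boundary (eps -> 0.5, or T1 -> 0 which also flattens the model) with
  # zero residual, and is flagged
  f <- fit_t1_voxel(rep(0.9, 8), proto)
  expect_true(f$valid)
  expect_true(f$boundary_active)
  expect_lt(f$residual_norm, 1e-8)
  expect_true(abs(f$eps - 0.5) < 1e-4 || f$t1_ms < 1)
})

test_that("T1 is recovered within 2% under Rician noise at SNR 50", {
  proto <- ir_protocol()
  ti <- ir_ti_full(proto)
  t1h <- with_seed(101, replicate(500, {
    y <- add_rician(ir_signal(1, 2600, 0.05, ti), 1 / 50)
    fit_t1_voxel(y, proto)$t1_ms
  }))
  expect_lt(abs(stats::median(t1h) - 2600) / 2600, 0.02)
})

test_that("freeing eps never increases the residual (nested models)", {
  proto <- ir_protocol()
  ti <- ir_ti_full(proto)
  with_seed(11, for (i in 1:10) {
    y <- add_rician(ir_signal(1, stats::runif(1, 1500, 3500),
                              stats::runif(1, 0, 0.3), ti), 1 / 60)
    f3 <- fit_t1_voxel(y, proto)
    f2 <- fit_t1_voxel(y, proto, fix_eps = 0)
    expect_lte(f3$residual_norm, f2$residual_norm * (1 + 1e-6) + 1e-9)
  })
})

test_that("two- and three-parameter fits agree on eps-free data", {
  proto <- ir_protocol()
  ti <- ir_ti_full(proto)
  y <- abs(ir_signal(1, 2400, 0, ti))
  f3 <- fit_t1_voxel(y, proto)
  f2 <- fit_t1_voxel(y, proto, fix_eps = 0)
  expect_equal(f3$t1_ms, f2$t1_ms, tolerance = 1e-3)
})

test_that("the noiseless objective is minimised at the generating point", {
  proto <- ir_protocol()
  ti <- ir_ti_full(proto)
  ssq <- function(p, y) sum((abs(ir_signal(p[1], p[2], p[3], ti)) - y)^2)
  with_seed(21, for (i in 1:10) {
    gen <- c(1, stats::runif(1, 1200, 4000), stats::runif(1, 0.01, 0.4))
    y <- abs(ir_signal(gen[1], gen[2], gen[3], ti))
    fit <- fit_t1_voxel(y, proto)
    # coarse grid-search oracle around and away from the truth
    grid <- expand.grid(s0 = c(0.8, 1, 1.2),
                        t1 = seq(800, 5000, by = 300),
                        eps = c(0, 0.1, 0.25, 0.45))
    vals <- apply(grid, 1, ssq, y = y)
    expect_lte(ssq(c(fit$s0, fit$t1_ms, fit$eps), y), min(vals) + 1e-12)
  })
})

test_that("map fitting recovers a noiseless phantom and flags QC", {
  truth <- noiseless_phantom()
  ir <- noiseless_ir()
  mask <- truth$labels$labels > 0
  m <- fit_t1_map(ir$images, mask)
  relerr <- abs(m$t1_ms[mask] - truth$t1_ms[mask]) / truth$t1_ms[mask]
  expect_lt(stats::median(relerr), 0.005)
  expect_true(all(m$qc[mask] == 0))
  expect_true(all(is.na(m$t1_ms[!mask])))
  # empty mask gives an empty map
  e <- fit_t1_map(ir$images, matrix(FALSE, nrow(mask), ncol(mask)))
  expect_true(all(is.na(e$t1_ms)))
})

test_that("spatially varying inversion inefficiency does not bias T1", {
  # imperfect-inversion analog: eps varies smoothly up to 0.4 across the
  # slice; including eps in the fit keeps T1 unbiased
  spec <- phantom_spec(shape = c(96, 96), noise_snr = Inf,
                       eps_range = c(0.05, 0.4))
  truth <- make_phantom(spec, seed = 8)
  ir <- simulate_ir_series(truth, seed = 9)
  mask <- truth$labels$labels > 0
  m <- fit_t1_map(ir$images, mask)
  relerr <- abs(m$t1_ms[mask] - truth$t1_ms[mask]) / truth$t1_ms[mask]
  expect_lt(stats::median(relerr), 0.01)
  # and the eps map itself is recovered
  expect_lt(stats::median(abs(m$eps[mask] - truth$eps[mask])), 0.01)
})
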