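#' Default coarse dictionary axes
#'
#' 32 T2 values equally spaced in 10-480 ms, 24 T1 values in 500-4000 ms and
#' 16 relative-B1 values in 0.2-1.5.
#'
#' @return A list with elements `t2_ms`, `t1_ms`, `b1`.
#' @export
default_dict_axes <- function() {
  list(t2_ms = seq(10, 480, length.out = 32),
       t1_ms = seq(500, 4000, length.out = 24),
       b1 = seq(0.2, 1.5, length.out = 16))
}

#' Build a TSE signal dictionary by Bloch simulation
#'
#' Simulates [simulate_echo_train()] for every `(t2, t1, b1)` combination and
#' stores the k-space-centre echo amplitudes ([extract_center_echoes()]) as
#' dictionary atoms. Grid corners with `t1 <= t2` are physically implausible
#' but are simulated anyway (the Bloch equations remain defined) so the grid
#' stays complete for trilinear interpolation; they are flagged in
#' `invalid_corners`.
#'
#' @param proto A `tse_protocol`.
#' @param grid An `isochromat_grid`.
#' @param pulses A `pulse_model`.
#' @param axes Dictionary axes as from [default_dict_axes()].
#' @return An object of class `t2_dictionary` with an
#'   `atoms[t2, t1, b1, echo]` array.
#' @export
build_dictionary <- function(proto = tse_protocol(), grid = isochromat_grid(),
                             pulses = pulse_model(), axes = default_dict_axes()) {
  stopifnot(is.list(axes), all(c("t2_ms", "t1_ms", "b1") %in% names(axes)))
  nt2 <- length(axes$t2_ms); nt1 <- length(axes$t1_ms); nb1 <- length(axes$b1)
  ne <- length(proto$echo_indices)
  atoms <- array(NA_real_, c(nt2, nt1, nb1, ne))
  esp_s <- proto$echo_spacing_ms / 1000
  for (ib in seq_len(nb1)) {
    ops <- .train_operators(proto, grid, pulses, axes$b1[ib])
    for (it1 in seq_len(nt1)) {
      t1_s <- axes$t1_ms[it1] / 1000
      for (it2 in seq_len(nt2)) {
        train <- .run_train(ops, t1_s, axes$t2_ms[it2] / 1000, proto$etl,
                            esp_s)
        atoms[it2, it1, ib, ] <- train[proto$echo_indices]
      }
    }
  }
  invalid <- outer(axes$t2_ms, axes$t1_ms, function(t2, t1) t1 <= t2)
  cfg <- list(proto = unclass(proto), grid = grid[c("n_readout", "n_slice",
              "extent_readout_mm", "extent_slice_mm")], pulses = unclass(pulses))
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(as.character(cfg_json), tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  structure(list(axes = axes, atoms = atoms, fine = FALSE,
                 invalid_corners = invalid, echo_times_ms = proto$te_centers_ms,
                 echo_indices = proto$echo_indices,
                 provenance = list(config = cfg, config_hash = hash)),
            class = "t2_dictionary")
}

#' Interpolate a coarse dictionary to the fine grid
#'
#' Atoms are interpolated trilinearly in `(t2, t1, b1)` parameter space onto
#' a fine grid with steps of 1 ms in T2, 10 ms in T1 and 0.01 in relative B1.
#' The fine dictionary is evaluated lazily ([dict_atoms()]) so the full fine
#' grid (about 22 million atoms at default axes) is never materialized.
#'
#' @param d A coarse `t2_dictionary`.
#' @param t2_step_ms,t1_step_ms,b1_step Fine grid steps.
#' @return An object of class `t2_dictionary_fine`.
#' @export
interpolate_dictionary <- function(d, t2_step_ms = 1, t1_step_ms = 10,
                                   b1_step = 0.01) {
  stopifnot(inherits(d, "t2_dictionary"))
  ax <- d$axes
  fine <- list(
    t2_ms = seq(min(ax$t2_ms), max(ax$t2_ms), by = t2_step_ms),
    t1_ms = seq(min(ax$t1_ms), max(ax$t1_ms), by = t1_step_ms),
    b1 = seq(min(ax$b1), max(ax$b1), length.out =
               round((max(ax$b1) - min(ax$b1)) / b1_step) + 1))
  structure(list(coarse = d, fine_axes = fine, fine = TRUE,
                 provenance = d$provenance),
            class = "t2_dictionary_fine")
}

# Linear interpolation weights of query points q on a sorted axis x.
.interp_weights <- function(x, q) {
  if (any(q < min(x) - 1e-9) || any(q > max(x) + 1e-9))
    stop("query outside the coarse dictionary hull")
  q <- pmin(pmax(q, min(x)), max(x))
  i <- findInterval(q, x, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(x) - 1L)
  w <- (q - x[i]) / (x[i + 1] - x[i])
  list(i = i, w = w)
}

#' Evaluate fine-dictionary atoms at arbitrary parameter combinations
#'
#' Trilinear interpolation of the coarse atoms; exact at coarse nodes.
#'
#' @param fd A `t2_dictionary_fine` (or coarse `t2_dictionary`).
#' @param t2_ms,t1_ms,b1 Parameter vectors (recycled to a common length).
#' @return A matrix with one row per query and one column per echo.
#' @export
dict_atoms <- function(fd, t2_ms, t1_ms, b1) {
  d <- if (inherits(fd, "t2_dictionary_fine")) fd$coarse else fd
  n <- max(length(t2_ms), length(t1_ms), length(b1))
  t2_ms <- rep_len(t2_ms, n); t1_ms <- rep_len(t1_ms, n); b1 <- rep_len(b1, n)
  w2 <- .interp_weights(d$axes$t2_ms, t2_ms)
  w1 <- .interp_weights(d$axes$t1_ms, t1_ms)
  wb <- .interp_weights(d$axes$b1, b1)
  dims <- dim(d$atoms)
  ne <- dims[4]
  out <- matrix(0, n, ne)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wt <- (if (a == 1) w2$w else 1 - w2$w) *
          (if (b == 1) w1$w else 1 - w1$w) *
          (if (cc == 1) wb$w else 1 - wb$w)
    idx <- cbind(w2$i + a, w1$i + b, wb$i + cc)
    for (e in seq_len(ne))
      out[, e] <- out[, e] + wt * d$atoms[cbind(idx, e)]
  }
  out
}

# Fine-grid T2 profile at fixed (t1, b1): matrix [fine t2 x echo], optionally
# unit-normalized rows. Used as the matching subset.
.dict_t2_profile <- function(fd, t1_ms, b1, normalize = TRUE) {
  stopifnot(inherits(fd, "t2_dictionary_fine"))
  t2 <- fd$fine_axes$t2_ms
  m <- dict_atoms(fd, t2, rep(t1_ms, length(t2)), rep(b1, length(t2)))
  if (normalize) {
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- 1
    m <- m / nrm
  }
  m
}

#' Match a measured signal vector to the dictionary
#'
#' Restricts the fine dictionary to the nearest fine-grid B1 node and the
#' assumed T1, then returns the fine-grid T2 maximizing the normalized inner
#' product (cosine similarity) between atom and signal.
#'
#' @param signals Non-negative signal vector, one entry per k-space-centre
#'   echo.
#' @param b1_measured Measured relative B1 at the voxel.
#' @param fd A `t2_dictionary_fine`.
#' @param t1_assumed_ms Assumed T1 in ms (default 2600).
#' @return A list with `t2_ms`, `score`, `b1_used`, `t1_assumed_ms`, `valid`.
#' @export
match_t2 <- function(signals, b1_measured, fd, t1_assumed_ms = 2600) {
  stopifnot(inherits(fd, "t2_dictionary_fine"))
  if (any(signals < 0)) stop("signals must be non-negative")
  if (all(signals == 0) || anyNA(signals))
    return(list(t2_ms = NA_real_, score = NA_real_, b1_used = NA_real_,
                t1_assumed_ms = t1_assumed_ms, valid = FALSE))
  res <- match_t2_batch(matrix(signals, nrow = 1), b1_measured, fd, t1_assumed_ms)
  list(t2_ms = res$t2_ms[1], score = res$score[1], b1_used = res$b1_used[1],
       t1_assumed_ms = t1_assumed_ms, valid = TRUE)
}

#' Match many signal vectors at once
#'
#' Vectorized form of [match_t2()]: signals are grouped by their nearest
#' fine-grid B1 node and matched against the corresponding T2 profile by one
#' matrix product per group.
#'
#' @param signals Matrix with one row per voxel/sample, one column per echo.
#' @param b1_measured Vector of measured relative B1 values (recycled).
#' @param fd A `t2_dictionary_fine`.
#' @param t1_assumed_ms Assumed T1 in ms; scalar or per-row vector.
#' @return A list of vectors `t2_ms`, `score`, `b1_used`.
#' @export
match_t2_batch <- function(signals, b1_measured, fd, t1_assumed_ms = 2600) {
  stopifnot(inherits(fd, "t2_dictionary_fine"), is.matrix(signals))
  n <- nrow(signals)
  b1_measured <- rep_len(b1_measured, n)
  t1_assumed_ms <- rep_len(t1_assumed_ms, n)
  fb <- fd$fine_axes$b1
  ft1 <- fd$fine_axes$t1_ms
  if (any(b1_measured < min(fb) - 1e-9) || any(b1_measured > max(fb) + 1e-9))
    stop("b1_measured outside the fine B1 grid")
  ib <- pmin(pmax(round((b1_measured - fb[1]) / (fb[2] - fb[1])) + 1, 1), length(fb))
  it1 <- pmin(pmax(round((t1_assumed_ms - ft1[1]) / (ft1[2] - ft1[1])) + 1, 1), length(ft1))
  t2_ms <- numeric(n); score <- numeric(n)
  nrm <- sqrt(rowSums(signals^2))
  ok <- nrm > 0 & !is.na(nrm)
  grp <- split(seq_len(n)[ok], list(ib[ok], it1[ok]), drop = TRUE)
  for (g in grp) {
    prof <- .dict_t2_profile(fd, ft1[it1[g[1]]], fb[ib[g[1]]])
    sc <- prof %*% t(signals[g, , drop = FALSE] / nrm[g])
    best <- max.col(t(sc), ties.method = "first")
    t2_ms[g] <- fd$fine_axes$t2_ms[best]
    score[g] <- sc[cbind(best, seq_along(g))]
  }
  t2_ms[!ok] <- NA_real_; score[!ok] <- NA_real_
  list(t2_ms = t2_ms, score = score, b1_used = fb[ib])
}

#' Bias of T2 estimation under a fixed-T1 assumption
#'
#' Randomly samples entries of the fine dictionary, re-estimates T2 with T1
#' fixed (default 2.6 s) and the true B1, and reports the relative bias
#' `(t2_hat - t2) / t2` per sample, plus a summary binned to the nearest
#' coarse (T1, B1) nodes (max and 95th percentile of |bias| per bin).
#'
#' @param fd A `t2_dictionary_fine`.
#' @param n_samples Number of fine-grid entries to sample (with replacement).
#' @param t1_assumed_ms Fixed T1 used for matching, ms.
#' @param seed RNG seed recorded in the output.
#' @return A list with `samples` (data frame), `by_region` (binned summary),
#'   `n_samples`, `t1_assumed_ms`, `seed`.
#' @export
estimate_fixed_t1_bias <- function(fd, n_samples = 200000,
                                   t1_assumed_ms = 2600, seed = 1) {
  stopifnot(inherits(fd, "t2_dictionary_fine"))
  ax <- fd$fine_axes
  samp <- with_seed(seed, list(
    t2 = ax$t2_ms[sample.int(length(ax$t2_ms), n_samples, replace = TRUE)],
    t1 = ax$t1_ms[sample.int(length(ax$t1_ms), n_samples, replace = TRUE)],
    b1 = ax$b1[sample.int(length(ax$b1), n_samples, replace = TRUE)]))
  atoms <- dict_atoms(fd, samp$t2, samp$t1, samp$b1)
  m <- match_t2_batch(atoms, samp$b1, fd, t1_assumed_ms)
  bias <- (m$t2_ms - samp$t2) / samp$t2
  cax <- if (inherits(fd$coarse, "t2_dictionary")) fd$coarse$axes else fd$coarse$axes
  nearest <- function(x, nodes) nodes[pmin(pmax(findInterval(x, nodes +
    c(diff(nodes) / 2, Inf)) + 1, 1), length(nodes))]
  t1_bin <- nearest(samp$t1, cax$t1_ms)
  b1_bin <- nearest(samp$b1, cax$b1)
  samples <- data.frame(t2_ms = samp$t2, t1_ms = samp$t1, b1 = samp$b1,
                        t2_hat_ms = m$t2_ms, bias = bias,
                        t1_bin_ms = t1_bin, b1_bin = b1_bin)
  agg <- aggregate(abs(bias) ~ t1_bin_ms + b1_bin, data = samples,
                   FUN = function(x) c(max = max(x),
                                       p95 = unname(stats::quantile(x, 0.95)),
                                       n = length(x)))
  by_region <- data.frame(agg[1:2], max_abs_bias = agg[[3]][, "max"],
                          p95_abs_bias = agg[[3]][, "p95"], n = agg[[3]][, "n"])
  list(samples = samples, by_region = by_region, n_samples = n_samples,
       t1_assumed_ms = t1_assumed_ms, seed = seed)
}

#' Relative-bias bound over a (T1, B1) region
#'
#' Summarises the fixed-T1 bias study over a parameter region of interest.
#' The default statistic is the 95th percentile of `|bias|` over all region
#' samples: a robust region-wise bound. The pointwise sample maximum is
#' dominated by fine-grid quantisation at very short T2 (at T2 = 10 ms a
#' single 1-ms grid step is already a 10% relative error), so it bounds the
#' grid, not the fixed-T1 assumption; it is still available via
#' `statistic = "max"`, as is the worst per-(T1, B1)-cell median bias
#' (`"cell_median_max"`).
#'
#' @param bias Result of [estimate_fixed_t1_bias()].
#' @param t1_range_ms Open interval of true T1, ms.
#' @param b1_min Lower bound (exclusive) on relative B1.
#' @param statistic One of `"p95"`, `"max"`, `"cell_median_max"`.
#' @return The chosen statistic of relative bias in the region, as a
#'   fraction.
#' @export
max_bias_in_region <- function(bias, t1_range_ms = c(2000, 3500), b1_min = 0.5,
                               statistic = c("p95", "max", "cell_median_max")) {
  statistic <- match.arg(statistic)
  s <- bias$samples
  s <- s[s$t1_ms > t1_range_ms[1] & s$t1_ms < t1_range_ms[2] &
           s$b1 > b1_min, , drop = FALSE]
  if (!nrow(s)) return(NA_real_)
  switch(statistic,
         p95 = unname(stats::quantile(abs(s$bias), 0.95)),
         max = max(abs(s$bias)),
         cell_median_max = {
           cm <- stats::aggregate(bias ~ t1_bin_ms + b1_bin, data = s,
                                  FUN = stats::median)
           max(abs(cm$bias))
         })
}

#' Voxelwise dictionary T2 fitting of a multi-TE image stack
#'
#' @param images Array `[nrow, ncol, n_echo]` of echo images.
#' @param b1map Matrix of relative B1, same in-plane shape.
#' @param mask Logical matrix of voxels to fit.
#' @param fd A `t2_dictionary_fine`.
#' @param t1_assumed_ms Assumed T1: scalar, or a matrix for voxelwise T1.
#' @return A list of matrices `t2_ms`, `score`, plus `valid` and the inputs'
#'   shape; voxels outside the mask are `NA`.
#' @export
fit_t2_map <- function(images, b1map, mask, fd, t1_assumed_ms = 2600) {
  stopifnot(length(dim(images)) == 3)
  dm <- dim(images)[1:2]
  if (!all(dim(b1map) == dm) || !all(dim(mask) == dm))
    stop("images, b1map and mask shapes do not match")
  if (is.matrix(t1_assumed_ms) && !all(dim(t1_assumed_ms) == dm))
    stop("voxelwise t1_assumed_ms shape does not match images")
  idx <- which(mask)
  t2 <- matrix(NA_real_, dm[1], dm[2])
  sc <- matrix(NA_real_, dm[1], dm[2])
  valid <- matrix(FALSE, dm[1], dm[2])
  if (length(idx)) {
    sig <- apply(images, 3, function(x) x[idx])
    if (!is.matrix(sig)) sig <- matrix(sig, nrow = 1)
    t1v <- if (is.matrix(t1_assumed_ms)) t1_assumed_ms[idx] else t1_assumed_ms
    res <- match_t2_batch(sig, b1map[idx], fd, t1v)
    t2[idx] <- res$t2_ms
    sc[idx] <- res$score
    valid[idx] <- !is.na(res$t2_ms)
  }
  list(t2_ms = t2, score = sc, valid = valid)
}
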