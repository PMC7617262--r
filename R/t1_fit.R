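#' Inversion-recovery signal model with inversion inefficiency
#'
#' `s0 * (1 - 2 * (1 - eps) * exp(-ti / t1))`. The inefficiency term `eps`
#' allows the signal at `ti -> 0` to exceed `-s0`, absorbing imperfect
#' inversion and the fast early recovery seen at ultrahigh field. `ti = Inf`
#' denotes the image acquired without an inversion pulse (signal `s0`).
#'
#' @param s0 Fully recovered signal amplitude.
#' @param t1_ms Longitudinal relaxation time, ms.
#' @param eps Inversion inefficiency in `[0, 0.5)`.
#' @param ti_s Inversion delay(s) in seconds; `Inf` for no inversion.
#' @return Signed signal; the magnitude is taken separately by the fitter.
#' @export
ir_signal <- function(s0, t1_ms, eps, ti_s) {
  stopifnot(all(t1_ms > 0), all(ti_s >= 0))
  out <- s0 * (1 - 2 * (1 - eps) * exp(-ti_s / (t1_ms / 1000)))
  out[is.infinite(ti_s)] <- s0
  out
}

# residual between |model| and measured magnitudes
.ir_residual <- function(par, ti_s, y) {
  abs(ir_signal(par[1], par[2], par[3], ti_s)) - y
}

#' Fit the inversion-recovery model to one voxel's magnitude signals
#'
#' Bound-constrained least squares of `|ir_signal|` against the measured
#' magnitudes, using Levenberg-Marquardt from multiple starts (the magnitude
#' objective is multimodal near the null point) and keeping the best
#' objective. Bounds: `0 < s0 < 1.3 * S_noinv`, `0 < t1 < 6000` ms,
#' `0 < eps < 0.5`.
#'
#' @param signals Non-negative magnitudes, one per entry of `ti_s`.
#' @param proto An `ir_protocol` (supplies `ti_s` via [ir_ti_full()]) or
#'   `NULL` if `ti_s` is given.
#' @param ti_s Optional explicit inversion times (seconds, `Inf` =
#'   no inversion); overrides the protocol list.
#' @param starts_t1_ms,starts_eps Multi-start grids.
#' @param fix_eps Optional fixed inversion-inefficiency value: the fit then
#'   has two free parameters (`s0`, `t1`); used for nested-model
#'   comparisons.
#' @param early_stop_tol Relative residual norm below which remaining starts
#'   are skipped (exact-data shortcut).
#' @return A list: `s0`, `t1_ms`, `eps`, `residual_norm`, `n_images_used`,
#'   `valid`, `boundary_active`, `converged`.
#' @export
fit_t1_voxel <- function(signals, proto = ir_protocol(), ti_s = NULL,
                         starts_t1_ms = c(1000, 2600, 4500),
                         starts_eps = c(0.01, 0.2), fix_eps = NULL,
                         early_stop_tol = 1e-8) {
  if (is.null(ti_s)) ti_s <- ir_ti_full(proto)
  if (length(signals) != length(ti_s))
    stop("signals and inversion-time list differ in length")
  keep <- !is.na(signals)
  signals <- signals[keep]; ti_s <- ti_s[keep]
  invalid <- list(s0 = NA_real_, t1_ms = NA_real_, eps = NA_real_,
                  residual_norm = NA_real_, n_images_used = sum(keep),
                  valid = FALSE, boundary_active = FALSE, converged = FALSE)
  if (sum(keep) < 4 || !any(is.infinite(ti_s)) || all(signals == 0))
    return(invalid)
  if (any(signals < 0)) stop("magnitude signals must be non-negative")
  s_noinv <- mean(signals[is.infinite(ti_s)])
  if (s_noinv <= 0) return(invalid)
  lower <- c(1e-9, 1e-3, 1e-9)
  upper <- c(1.3 * s_noinv, 6000, 0.5)
  fixed <- !is.null(fix_eps)
  if (fixed) starts_eps <- fix_eps
  best <- NULL
  scale2 <- sum(signals^2)
  for (t1s in starts_t1_ms) for (es in starts_eps) {
    fit <- try(if (fixed) {
      minpack.lm::nls.lm(
        par = c(s_noinv, t1s), lower = lower[1:2], upper = upper[1:2],
        fn = function(p, ti_s, y) .ir_residual(c(p, fix_eps), ti_s, y),
        ti_s = ti_s, y = signals,
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-8,
                                             maxiter = 200))
    } else {
      minpack.lm::nls.lm(
        par = c(s_noinv, t1s, es), lower = lower, upper = upper,
        fn = .ir_residual, ti_s = ti_s, y = signals,
        control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-8,
                                             maxiter = 200))
    }, silent = TRUE)
    if (inherits(fit, "try-error")) next
    ssq <- sum(fit$fvec^2)
    if (is.null(best) || ssq < best$ssq) best <- list(fit = fit, ssq = ssq)
    if (ssq <= early_stop_tol * scale2) break
  }
  if (is.null(best)) return(invalid)
  p <- best$fit$par
  if (fixed) p <- c(p, fix_eps)
  at_bound <- (p[2] <= lower[2] * (1 + 1e-6)) || (p[2] >= upper[2] * (1 - 1e-6)) ||
    (p[3] <= 1e-6) || (p[3] >= upper[3] - 1e-6) ||
    (p[1] >= upper[1] * (1 - 1e-6))
  list(s0 = p[1], t1_ms = p[2], eps = p[3],
       residual_norm = sqrt(best$ssq), n_images_used = sum(keep),
       valid = TRUE, boundary_active = at_bound,
       converged = best$fit$info %in% 1:4)
}

#' Voxelwise inversion-recovery T1 mapping
#'
#' Applies [fit_t1_voxel()] inside a mask. Voxels flagged invalid or with an
#' active bound constraint are recorded in the `qc` channel
#' (0 = ok, 1 = boundary-active, 2 = invalid).
#'
#' @param image_stack Array `[nrow, ncol, n_ti]`, ordered like `ti_s`.
#' @param mask Logical matrix of voxels to fit.
#' @param proto An `ir_protocol`.
#' @param ti_s Optional explicit inversion times overriding the protocol.
#' @return A list of matrices `t1_ms`, `s0`, `eps`, `residual`, `qc` plus
#'   `n_images_used`.
#' @export
fit_t1_map <- function(image_stack, mask, proto = ir_protocol(), ti_s = NULL) {
  stopifnot(length(dim(image_stack)) == 3)
  dm <- dim(image_stack)[1:2]
  if (!all(dim(mask) == dm)) stop("mask shape does not match image stack")
  if (is.null(ti_s)) ti_s <- ir_ti_full(proto)
  if (dim(image_stack)[3] != length(ti_s))
    stop("stack depth does not match inversion-time list")
  t1 <- s0 <- eps <- res <- matrix(NA_real_, dm[1], dm[2])
  qc <- matrix(NA_integer_, dm[1], dm[2])
  idx <- which(mask)
  if (length(idx)) {
    sig <- apply(image_stack, 3, function(x) x[idx])
    if (!is.matrix(sig)) sig <- matrix(sig, nrow = 1)
    for (v in seq_along(idx)) {
      f <- fit_t1_voxel(sig[v, ], proto = NULL, ti_s = ti_s)
      t1[idx[v]] <- f$t1_ms; s0[idx[v]] <- f$s0; eps[idx[v]] <- f$eps
      res[idx[v]] <- f$residual_norm
      qc[idx[v]] <- if (!f$valid) 2L else if (f$boundary_active) 1L else 0L
    }
  }
  list(t1_ms = t1, s0 = s0, eps = eps, residual = res, qc = qc,
       n_images_used = length(ti_s))
}
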