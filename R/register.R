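#' Rigid in-plane registration of an image series
#'
#' Aligns each image of a same-contrast 2D series to a reference image by an
#' in-plane rigid transform (translation and rotation), minimizing the
#' mean-squared error of intensity-normalized images via a multiresolution
#' grid search followed by Nelder-Mead refinement.
#'
#' @param image_stack Array `[nrow, ncol, n_images]`.
#' @param reference_index Index of the reference image.
#' @param exclude Indices of images to drop (manual rejection); the output
#'   stack omits them.
#' @param max_shift_px,max_rot_deg Search bounds.
#' @return A list: `stack` (registered images), `transforms` (data frame of
#'   `dx`, `dy`, `theta_deg` applied to align each retained image),
#'   `kept` (retained indices), `reference_index`.
#' @export
register_series <- function(image_stack, reference_index = 1, exclude = integer(),
                            max_shift_px = 10, max_rot_deg = 10) {
  stopifnot(length(dim(image_stack)) == 3)
  n <- dim(image_stack)[3]
  stopifnot(reference_index >= 1, reference_index <= n)
  if (reference_index %in% exclude) stop("cannot exclude the reference image")
  kept <- setdiff(seq_len(n), as.integer(exclude))
  ref <- image_stack[, , reference_index]
  out <- image_stack[, , kept, drop = FALSE]
  tf <- data.frame(dx = numeric(length(kept)), dy = 0, theta_deg = 0)
  refn <- .znorm(ref)
  for (m in seq_along(kept)) {
    i <- kept[m]
    if (i == reference_index) next
    mov <- image_stack[, , i]
    if (stats::sd(mov) == 0 || stats::sd(ref) == 0) {
      warning("degenerate (constant) image; identity transform used")
      next
    }
    p <- .register_pair(refn, .znorm(mov), max_shift_px, max_rot_deg)
    tf$dx[m] <- p[1]; tf$dy[m] <- p[2]; tf$theta_deg[m] <- p[3]
    out[, , m] <- apply_rigid(mov, p[1], p[2], p[3], fill = 0)
  }
  list(stack = out, transforms = tf, kept = kept,
       reference_index = reference_index)
}

.znorm <- function(x) (x - mean(x)) / stats::sd(x)

# MSE over pixels where the warped image is valid
.reg_cost <- function(p, fixed, moving) {
  w <- apply_rigid(moving, p[1], p[2], p[3], fill = NA_real_)
  ok <- !is.na(w)
  if (sum(ok) < 0.25 * length(w)) return(Inf)
  mean((w[ok] - fixed[ok])^2)
}

.downsample2 <- function(img, f) {
  nr <- floor(nrow(img) / f) * f; nc <- floor(ncol(img) / f) * f
  img <- img[seq_len(nr), seq_len(nc)]
  blk <- array(img, c(f, nr / f, f, nc / f))
  apply(blk, c(2, 4), mean)
}

.register_pair <- function(fixed, moving, max_shift_px, max_rot_deg) {
  f <- 4
  fl <- .downsample2(fixed, f); ml <- .downsample2(moving, f)
  sh <- seq(-max_shift_px, max_shift_px, by = 2) / f
  ro <- seq(-max_rot_deg, max_rot_deg, by = 2.5)
  best <- c(0, 0, 0); bc <- Inf
  for (r in ro) for (x in sh) for (y in sh) {
    cst <- .reg_cost(c(x, y, r), fl, ml)
    if (cst < bc) { bc <- cst; best <- c(x, y, r) }
  }
  start <- c(best[1] * f, best[2] * f, best[3])
  # refine at half resolution, then polish at full resolution
  f2 <- 2
  fm <- .downsample2(fixed, f2); mm <- .downsample2(moving, f2)
  opt <- stats::optim(c(start[1] / f2, start[2] / f2, start[3]), .reg_cost,
                      fixed = fm, moving = mm, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 200))
  opt2 <- stats::optim(c(opt$par[1] * f2, opt$par[2] * f2, opt$par[3]),
                       .reg_cost, fixed = fixed, moving = moving,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 150))
  opt2$par
}

#' Invert an in-plane rigid transform
#'
#' Returns the parameters that undo `apply_rigid(img, dx, dy, theta_deg)`.
#'
#' @param dx,dy,theta_deg Forward transform parameters.
#' @return Named vector `dx`, `dy`, `theta_deg` of the inverse.
#' @export
invert_rigid <- function(dx, dy, theta_deg) {
  th <- -theta_deg * pi / 180
  c(dx = -(cos(th) * dx - sin(th) * dy),
    dy = -(sin(th) * dx + cos(th) * dy),
    theta_deg = -theta_deg)
}
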