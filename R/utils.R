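#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state, so seeded helpers do not disturb
#' the caller's random stream. A `NULL` seed leaves the current stream in
#' place (and advances it).
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Truncated normal draws by inverse-CDF sampling
#'
#' @param n Number of draws.
#' @param mean,sd Location and scale of the untruncated normal.
#' @param lower,upper Truncation bounds.
#' @return Numeric vector of length `n`.
#' @export
rnorm_trunc <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(upper > lower, sd > 0)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Add Rician noise to a noise-free magnitude signal
#'
#' The magnitude of a complex Gaussian perturbation: real channel carries the
#' signal, both channels receive independent noise of standard deviation
#' `sigma`.
#'
#' @param signal Noise-free (signed or magnitude) signal array.
#' @param sigma Gaussian channel noise SD.
#' @return Array of the same shape with Rician-distributed magnitudes.
#' @export
add_rician <- function(signal, sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(abs(signal))
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  array(out, dim = dim(signal) %||% n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply an in-plane rigid transform to a 2D image
#'
#' The image content is rotated by `theta_deg` about the image centre and
#' then translated by `(dx, dy)` pixels (columns, rows). Output pixels are
#' bilinearly interpolated; pixels mapping outside the input get `fill`.
#'
#' @param img Numeric matrix.
#' @param dx,dy Translation in pixels (column and row directions).
#' @param theta_deg Rotation angle in degrees, counter-clockwise.
#' @param fill Value for out-of-image samples.
#' @return Transformed matrix of the same shape.
#' @export
apply_rigid <- function(img, dx = 0, dy = 0, theta_deg = 0, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- theta_deg * pi / 180
  co <- cos(th); si <- sin(th)
  gx <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx - dx
  gy <- matrix(seq_len(nr), nr, nc) - cy - dy
  # inverse rotation back into source coordinates
  sx <- co * gx + si * gy + cx
  sy <- -si * gx + co * gy + cy
  bilinear_sample(img, sy, sx, fill = fill)
}

#' Bilinear sampling of a matrix at fractional (row, col) positions
#'
#' @param img Numeric matrix.
#' @param r,c Arrays of fractional row/column positions (1-based).
#' @param fill Value returned outside the image.
#' @return Array of sampled values shaped like `r`.
#' @export
bilinear_sample <- function(img, r, c, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  inside <- r0 >= 1 & r0 <= nr - 1 & c0 >= 1 & c0 <= nc - 1
  # clamp for safe indexing; overwritten with fill afterwards
  r0c <- pmin(pmax(r0, 1), nr - 1); c0c <- pmin(pmax(c0, 1), nc - 1)
  v00 <- img[cbind(as.vector(r0c), as.vector(c0c))]
  v10 <- img[cbind(as.vector(r0c + 1), as.vector(c0c))]
  v01 <- img[cbind(as.vector(r0c), as.vector(c0c + 1))]
  v11 <- img[cbind(as.vector(r0c + 1), as.vector(c0c + 1))]
  out <- (1 - as.vector(fr)) * ((1 - as.vector(fc)) * v00 + as.vector(fc) * v01) +
    as.vector(fr) * ((1 - as.vector(fc)) * v10 + as.vector(fc) * v11)
  out[!as.vector(inside)] <- fill
  array(out, dim = dim(r) %||% length(r))
}

#' Trilinear sampling of a 3D volume at fractional voxel indices
#'
#' @param vol 3D numeric array.
#' @param i,j,k Vectors of fractional 1-based indices along the three axes.
#' @param fill Value returned outside the volume.
#' @return Numeric vector of sampled values.
#' @export
trilinear_sample <- function(vol, i, j, k, fill = NA_real_) {
  d <- dim(vol)
  i0 <- floor(i); j0 <- floor(j); k0 <- floor(k)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  inside <- i0 >= 1 & i0 <= d[1] - 1 & j0 >= 1 & j0 <= d[2] - 1 &
    k0 >= 1 & k0 <= d[3] - 1
  # allow sampling exactly at the upper faces
  atmax <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  i0 <- pmin(pmax(i0, 1), d[1] - 1); j0 <- pmin(pmax(j0, 1), d[2] - 1)
  k0 <- pmin(pmax(k0, 1), d[3] - 1)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  out <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    w <- (if (a == 1) fi else 1 - fi) * (if (b == 1) fj else 1 - fj) *
      (if (cc == 1) fk else 1 - fk)
    out <- out + w * vol[cbind(i0 + a, j0 + b, k0 + cc)]
  }
  out[!(inside | atmax)] <- fill
  out
}
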