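#' Flip angle from a dual-TR actual flip-angle imaging (AFI) pair
#'
#' Under ideal spoiling and `TR1, TR2 << T1`, the AFI steady-state signal
#' ratio `r = s2 / s1` relates to the flip angle by
#' `theta = arccos((r * n - 1) / (n - r))` with `n = TR2 / TR1`. Arguments
#' pushed outside `[-1, 1]` by noise are clipped and flagged rather than
#' rejected.
#'
#' @param s1,s2 Steady-state signals at TR1 and TR2 (vectors or arrays).
#' @param n TR ratio (default 5, i.e. 117.5 / 23.5 ms).
#' @return A list: `theta_deg` (same shape as the input), `clipped`,
#'   `valid` (`FALSE` where `s1 <= 0`).
#' @export
afi_flip_angle <- function(s1, s2, n = 5) {
  stopifnot(n > 1)
  if (length(s1) != length(s2)) {
    nl <- max(length(s1), length(s2))
    s1 <- rep_len(s1, nl); s2 <- rep_len(s2, nl)
  }
  valid <- is.finite(s1) & is.finite(s2) & s1 > 0
  r <- ifelse(valid, s2 / s1, NA_real_)
  arg <- (r * n - 1) / (n - r)
  clipped <- valid & (arg < -1 | arg > 1)
  theta <- acos(pmin(pmax(arg, -1), 1)) * 180 / pi
  theta[!valid] <- NA_real_
  shape <- function(x) if (is.null(dim(s1))) as.vector(x)
                       else array(x, dim = dim(s1))
  list(theta_deg = shape(theta), clipped = shape(clipped),
       valid = shape(valid))
}

#' AFI forward signal ratio for a known flip angle
#'
#' The short-TR ideal-spoiling approximation
#' `r = (1 + n * cos(theta)) / (n + cos(theta))`; exact inverse of
#' [afi_flip_angle()].
#'
#' @param theta_deg Flip angle, degrees.
#' @param n TR ratio.
#' @return Signal ratio `s2 / s1`.
#' @export
afi_forward_ratio <- function(theta_deg, n = 5) {
  ct <- cos(theta_deg * pi / 180)
  (1 + n * ct) / (n + ct)
}

#' Relative transmit field from measured and nominal flip angles
#'
#' @param theta_deg Measured flip angle, degrees.
#' @param theta_nominal_deg Nominal flip angle, degrees (default 60).
#' @return `theta_deg / theta_nominal_deg`.
#' @export
relative_b1 <- function(theta_deg, theta_nominal_deg = 60) {
  stopifnot(theta_nominal_deg > 0)
  theta_deg / theta_nominal_deg
}

#' Relative-B1 volume from an AFI volume pair
#'
#' @param s1,s2 3D signal arrays at TR1 and TR2.
#' @param n TR ratio.
#' @param theta_nominal_deg Nominal flip angle, degrees.
#' @return A list: `b1rel` (3D array), `clipped`, `valid`.
#' @export
afi_b1_map <- function(s1, s2, n = 5, theta_nominal_deg = 60) {
  th <- afi_flip_angle(s1, s2, n)
  list(b1rel = relative_b1(th$theta_deg, theta_nominal_deg),
       clipped = th$clipped, valid = th$valid)
}

#' Axis-aligned volume geometry
#'
#' @param origin_mm World coordinates (mm) of the centre of voxel (1,1,1).
#' @param spacing_mm Voxel spacing (mm) along the three axes.
#' @return A list of class `vol_geometry`.
#' @export
vol_geometry <- function(origin_mm = c(0, 0, 0), spacing_mm = c(1, 1, 1)) {
  stopifnot(length(origin_mm) == 3, length(spacing_mm) == 3, all(spacing_mm > 0))
  structure(list(origin_mm = origin_mm, spacing_mm = spacing_mm),
            class = "vol_geometry")
}

#' Oblique 2D slice geometry
#'
#' Pixel (i, j) (row, column) sits at
#' `origin + (j-1) * spacing[1] * u + (i-1) * spacing[2] * v` in world mm.
#'
#' @param origin_mm World coordinates of the centre of pixel (1, 1).
#' @param u,v Unit direction vectors of the column and row axes.
#' @param spacing_mm In-plane pixel spacing `(du, dv)`, mm.
#' @param dims Slice dimensions `(nrow, ncol)`.
#' @return A list of class `slice_geometry`.
#' @export
slice_geometry <- function(origin_mm = c(0, 0, 0), u = c(1, 0, 0),
                           v = c(0, 1, 0), spacing_mm = c(0.8, 0.8),
                           dims = c(160, 160)) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  stopifnot(length(dims) == 2, all(spacing_mm > 0))
  structure(list(origin_mm = origin_mm, u = u, v = v,
                 spacing_mm = spacing_mm, dims = as.integer(dims)),
            class = "slice_geometry")
}

# world coordinates (n x 3) of every pixel of a slice, row-major over (i, j)
.slice_world_coords <- function(sg) {
  i <- rep(seq_len(sg$dims[1]), times = sg$dims[2])
  j <- rep(seq_len(sg$dims[2]), each = sg$dims[1])
  cbind(sg$origin_mm[1] + (j - 1) * sg$spacing_mm[1] * sg$u[1] +
          (i - 1) * sg$spacing_mm[2] * sg$v[1],
        sg$origin_mm[2] + (j - 1) * sg$spacing_mm[1] * sg$u[2] +
          (i - 1) * sg$spacing_mm[2] * sg$v[2],
        sg$origin_mm[3] + (j - 1) * sg$spacing_mm[1] * sg$u[3] +
          (i - 1) * sg$spacing_mm[2] * sg$v[3])
}

# continuous 1-based voxel indices of world points in an axis-aligned volume
.world_to_index <- function(xyz, vg) {
  sweep(sweep(xyz, 2, vg$origin_mm, "-"), 2, vg$spacing_mm, "/") + 1
}

#' Resample a B1 volume onto the mapping slice
#'
#' Trilinear resampling of a (coarser) axis-aligned relative-B1 volume onto
#' the 2D mapping-slice grid. Slice pixels falling outside the volume are
#' `NA` and flagged.
#'
#' @param b1_vol 3D array of relative B1.
#' @param vg The volume's `vol_geometry`.
#' @param sg The target `slice_geometry`.
#' @return A list: `b1rel` (matrix `dims`), `outside` (logical matrix).
#' @export
resample_b1_to_slice <- function(b1_vol, vg, sg) {
  stopifnot(length(dim(b1_vol)) == 3, inherits(vg, "vol_geometry"),
            inherits(sg, "slice_geometry"))
  idx <- .world_to_index(.slice_world_coords(sg), vg)
  vals <- trilinear_sample(b1_vol, idx[, 1], idx[, 2], idx[, 3], fill = NA_real_)
  b1 <- matrix(vals, sg$dims[1], sg$dims[2])
  if (all(is.na(b1))) stop("slice geometry is disjoint from the B1 volume")
  list(b1rel = b1, outside = is.na(b1))
}
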