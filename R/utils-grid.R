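# Low-level 3-D grid helpers shared by the phantom generator and the dose
# engine. All arrays are [nx, ny, nz] with x the lateral (beam) axis,
# y anterior-posterior, z cranio-caudal. Voxel centers are at
# origin + (index - 1) * spacing.

#' Translate a 3-D array by a constant offset
#'
#' Resamples `arr` so that its content moves by `shift_mm`: the output at
#' voxel position p equals the input at p - shift. Out-of-grid samples take
#' the fill value. Linear interpolation is separable (three 1-D passes,
#' equivalent to trilinear for a constant offset); nearest-neighbour rounds
#' the offset per axis, which keeps binary masks binary.
#'
#' @param arr 3-D numeric array.
#' @param shift_mm length-3 offset in mm (content moves by +shift).
#' @param spacing length-3 voxel spacing in mm.
#' @param method "linear" or "nearest".
#' @param fill value used outside the grid.
#' @return array of the same dimension.
#' @keywords internal
shift_grid <- function(arr, shift_mm, spacing, method = c("linear", "nearest"),
                       fill = 0) {
  method <- match.arg(method)
  stopifnot(length(dim(arr)) == 3L, length(shift_mm) == 3L)
  f <- shift_mm / spacing
  if (method == "nearest") f <- round(f)
  for (ax in 1:3) {
    if (f[ax] != 0) arr <- .shift_axis(arr, ax, f[ax], fill)
  }
  arr
}

# shift along one axis by fractional voxel offset f: out[i] = in[i - f]
.shift_axis <- function(arr, axis, f, fill) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- prod(dim(a)[-1])
  dim(a) <- c(n, m)
  k <- floor(f)
  t <- f - k
  src1 <- seq_len(n) - k       # integer part
  src2 <- src1 - 1L            # one further back (weight t)
  g1 <- .gather_rows(a, src1, fill)
  if (t == 0) {
    out <- g1
  } else {
    out <- (1 - t) * g1 + t * .gather_rows(a, src2, fill)
  }
  dim(out) <- dim(aperm(arr, perm))
  aperm(out, order(perm))
}

.gather_rows <- function(mat, rows, fill) {
  n <- nrow(mat)
  ok <- rows >= 1L & rows <= n
  out <- matrix(fill, n, ncol(mat))
  out[ok, ] <- mat[rows[ok], , drop = FALSE]
  out
}

#' Cumulative water-equivalent depth along the x axis
#'
#' Returns an array of WED (mm) at voxel centers for a beam travelling in
#' +x or -x. The half-voxel convention assigns each voxel center the
#' integral up to the center of that voxel: wed_i = (sum_{j<=i} spr_j -
#' spr_i / 2) * dx along the travel direction.
#'
#' @keywords internal
wed_field <- function(spr, dx, direction = 1L) {
  d <- dim(spr)
  a <- spr
  if (direction < 0) a <- a[d[1]:1, , , drop = FALSE]
  dim(a) <- c(d[1], prod(d[-1]))
  cs <- a
  for (i in 2:d[1]) cs[i, ] <- cs[i - 1L, ] + a[i, ]
  w <- (cs - a / 2) * dx
  dim(w) <- d
  if (direction < 0) w <- w[d[1]:1, , , drop = FALSE]
  w
}

# voxel-center physical coordinates along each axis
.axis_coords <- function(dim3, spacing, origin) {
  lapply(1:3, function(a) origin[a] + (seq_len(dim3[a]) - 1) * spacing[a])
}

# volume of a binary mask in mm^3
mask_volume <- function(mask, spacing) {
  sum(mask) * prod(spacing)
}

# smoothly terminated plateau factor Phi(q) with the far tails
# short-circuited (|q| > 7: error < 2e-12, negligible for dose)
.plateau_phi <- function(q) {
  p <- numeric(length(q))
  band <- q > -7 & q < 7
  p[band] <- stats::pnorm(q[band])
  p[q >= 7] <- 1
  p
}
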