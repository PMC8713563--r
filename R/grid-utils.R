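#' Diagonal voxel-to-mm affine
#'
#' Builds the 4x4 voxel-to-world matrix used throughout the package: a pure
#' scaling by the voxel edge length, with the world origin at voxel (1,1,1).
#' All images in a cohort must share one affine; no resampling is implemented.
#'
#' @param voxel_size_mm Voxel edge length in mm (isotropic), or a length-3
#'   vector of per-axis sizes.
#' @return A 4x4 numeric matrix.
#' @export
make_affine <- function(voxel_size_mm) {
  v <- rep_len(as.numeric(voxel_size_mm), 3L)
  stopifnot(all(v > 0))
  a <- diag(c(v, 1))
  a[1:3, 4] <- -v  # voxel index 1 maps to 0 mm
  a
}

#' Convert voxel indices to world (mm) coordinates
#'
#' @param idx Integer matrix with three columns (1-based voxel indices), or a
#'   length-3 vector.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return Numeric matrix with three columns of mm coordinates.
#' @export
vox_to_mm <- function(idx, affine) {
  if (is.null(dim(idx))) idx <- matrix(idx, nrow = 1L)
  h <- cbind(idx, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

# linear index -> (i,j,k) for a 3D grid
lin_to_coord <- function(lin, dims) {
  lin0 <- lin - 1L
  i <- lin0 %% dims[1L]
  j <- (lin0 %/% dims[1L]) %% dims[2L]
  k <- lin0 %/% (dims[1L] * dims[2L])
  cbind(i + 1L, j + 1L, k + 1L)
}

coord_to_lin <- function(xyz, dims) {
  (xyz[, 3L] - 1L) * dims[1L] * dims[2L] + (xyz[, 2L] - 1L) * dims[1L] + xyz[, 1L]
}

# neighbour displacement set for 6/18/26-connectivity
connectivity_offsets <- function(connectivity = 6L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  m <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6" = m == 1L,
    "18" = m >= 1L & m <= 2L,
    "26" = m >= 1L
  )
  g[keep, , drop = FALSE]
}

#' Label connected components of a voxel set
#'
#' Groups the supplied voxels into connected components under face (6),
#' edge (18) or corner (26) adjacency. Used for cluster formation after
#' voxel-wise thresholding.
#'
#' @param idx Linear indices (1-based, column-major) of the voxels to label,
#'   or a 3D logical array.
#' @param dims Length-3 grid dimensions (ignored when `idx` is an array).
#' @param connectivity 6, 18 or 26.
#' @return Integer vector of component labels (1..n_components), in the order
#'   of the input indices; labels are assigned in increasing order of each
#'   component's smallest linear index.
#' @export
label_components <- function(idx, dims = NULL, connectivity = 6L) {
  if (is.array(idx)) {
    dims <- dim(idx)
    idx <- which(idx)
  }
  idx <- as.integer(idx)
  n <- length(idx)
  if (n == 0L) return(integer(0))
  ord <- order(idx)
  sidx <- idx[ord]
  off <- connectivity_offsets(connectivity)
  xyz <- lin_to_coord(sidx, dims)
  labels <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (o in seq_len(nrow(off))) {
        nb <- xyz[v, ] + off[o, ]
        if (any(nb < 1L) || any(nb > dims)) next
        nlin <- coord_to_lin(matrix(nb, nrow = 1L), dims)
        pos <- findInterval(nlin, sidx)
        if (pos >= 1L && sidx[pos] == nlin && labels[pos] == 0L) {
          labels[pos] <- comp
          queue <- c(queue, pos)
        }
      }
    }
  }
  out <- integer(n)
  out[ord] <- labels
  out
}

#' Erode a binary mask by one voxel
#'
#' Single-pass morphological erosion with the 6-connected (face) structuring
#' element; voxels outside the grid count as background, so mask voxels on
#' the grid boundary are always removed.
#'
#' @param mask 3D logical array.
#' @return 3D logical array of the eroded mask.
#' @export
erode_mask <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  d <- dim(mask)
  out <- mask
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  ix <- 2:(d[1] + 1); iy <- 2:(d[2] + 1); iz <- 2:(d[3] + 1)
  out <- pad[ix, iy, iz] &
    pad[ix - 1, iy, iz] & pad[ix + 1, iy, iz] &
    pad[ix, iy - 1, iz] & pad[ix, iy + 1, iz] &
    pad[ix, iy, iz - 1] & pad[ix, iy, iz + 1]
  out
}

# 1D Gaussian kernel in voxel units; radius covers +-3.5 sigma
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma_vox))
  k <- exp(-0.5 * ((-r):r / sigma_vox)^2)
  k / sum(k)
}

# convolve a 3D array along one axis with zero padding at the edges
conv_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(arr * kernel)
  d <- dim(arr)
  out <- array(0, d)
  n <- d[axis]
  for (j in seq_along(kernel)) {
    o <- j - r - 1L  # offset in [-r, r]
    src_lo <- max(1L, 1L - o); src_hi <- min(n, n - o)
    if (src_lo > src_hi) next
    dst <- (src_lo + o):(src_hi + o)
    src <- src_lo:src_hi
    if (axis == 1L) {
      out[dst, , ] <- out[dst, , ] + kernel[j] * arr[src, , ]
    } else if (axis == 2L) {
      out[, dst, ] <- out[, dst, ] + kernel[j] * arr[, src, ]
    } else {
      out[, , dst] <- out[, , dst] + kernel[j] * arr[, , src]
    }
  }
  out
}

#' Mask-renormalised Gaussian smoothing of a 3D map
#'
#' Separable Gaussian convolution with sigma = FWHM / (2 sqrt(2 ln 2)) per
#' axis, renormalised over the mask so that no signal bleeds in from (or out
#' to) voxels outside the mask: the smoothed map is conv(x * m) / conv(m)
#' inside the mask and NA outside. NA voxels inside the mask are treated as
#' missing and excluded from the kernel normalisation.
#'
#' @param x 3D numeric array.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm.
#' @param voxel_size_mm Voxel edge length in mm (scalar or length-3).
#' @param mask 3D logical array; NULL means all voxels.
#' @return 3D numeric array, NA outside the mask.
#' @export
smooth_map <- function(x, fwhm_mm, voxel_size_mm, mask = NULL) {
  stopifnot(length(dim(x)) == 3L, fwhm_mm >= 0)
  v <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (is.null(mask)) mask <- array(TRUE, dim(x))
  if (min(fwhm_mm / v) < 0.5)
    warning("FWHM below half a voxel: smoothing is near-identity")
  eff <- mask & !is.na(x)
  xm <- x
  xm[!eff] <- 0
  num <- xm
  den <- array(as.numeric(eff), dim(x))
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / v
  for (ax in 1:3) {
    k <- gaussian_kernel_1d(sig[ax])
    num <- conv_axis(num, k, ax)
    den <- conv_axis(den, k, ax)
  }
  out <- array(NA_real_, dim(x))
  ok <- mask & den > .Machine$double.eps
  out[ok] <- num[ok] / den[ok]
  out
}
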