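#' 4D resting-state volume container
#'
#' Lightweight in-memory container used by every stage of the pipeline: the
#' (x, y, z, t) data array, the shared voxel-to-mm affine, the repetition
#' time, and the set of censored frame indices (empty until
#' [censor_frames()] runs).
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-mm matrix (see [make_affine()]).
#' @param tr_seconds Repetition time in seconds.
#' @param censored Integer vector of censored frame indices.
#' @return An object of class `volume4d`.
#' @export
volume4d <- function(data, affine, tr_seconds, censored = integer(0)) {
  stopifnot(length(dim(data)) == 4L, is.matrix(affine), all(dim(affine) == 4L),
            tr_seconds > 0)
  censored <- sort(unique(as.integer(censored)))
  if (length(censored) && (min(censored) < 1L || max(censored) > dim(data)[4L]))
    stop("censored frame indices out of range")
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds,
                 censored = censored),
            class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %d x %d x %d grid, %d frames, TR %.3g s, %d censored\n",
              d[1], d[2], d[3], d[4], x$tr_seconds, length(x$censored)))
  invisible(x)
}

#' @export
dim.volume4d <- function(x) dim(x$data)

# frames retained after censoring
retained_frames <- function(vol) {
  setdiff(seq_len(dim(vol$data)[4L]), vol$censored)
}

# voxel edge lengths from the affine
voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

# time x voxel matrix over a mask
mask_series <- function(vol, mask, frames = NULL) {
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  s <- t(m[which(mask), , drop = FALSE])
  if (!is.null(frames)) s <- s[frames, , drop = FALSE]
  s
}

# write a time x voxel matrix back into the 4D array over a mask
set_mask_series <- function(vol, mask, series) {
  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), d[4])
  m[which(mask), ] <- t(series)
  vol$data <- array(m, d)
  vol
}

#' Read a NIfTI image as a `volume4d`
#'
#' @param path Path to a 3D/4D NIfTI file (.nii or .nii.gz).
#' @param tr_seconds Repetition time; defaults to the header's time step
#'   when present.
#' @return A [volume4d()] object.
#' @export
read_volume4d <- function(path, tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  a <- structure(RNifti::xform(img), code = NULL, imagedim = NULL)
  pd <- RNifti::pixdim(img)
  if (is.null(tr_seconds)) tr_seconds <- if (length(pd) >= 4L && pd[4L] > 0) pd[4L] else 1
  d <- dim(img)
  if (length(d) == 3L) d <- c(d, 1L)
  volume4d(array(as.numeric(img), d), matrix(a[1:4, 1:4], 4, 4), tr_seconds)
}

#' Write a 3D/4D array or `volume4d` to NIfTI
#'
#' @param x 3D/4D numeric array, logical mask, or `volume4d`.
#' @param path Output path (.nii or .nii.gz).
#' @param affine 4x4 voxel-to-mm matrix (taken from `x` when a `volume4d`).
#' @param tr_seconds Frame duration stored in the header for 4D images.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, affine = NULL, tr_seconds = 1) {
  if (inherits(x, "volume4d")) {
    affine <- x$affine
    tr_seconds <- x$tr_seconds
    x <- x$data
  }
  stopifnot(!is.null(affine))
  img <- RNifti::asNifti(array(as.numeric(x), dim(x)))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  v <- voxel_size(affine)
  RNifti::pixdim(img) <- if (length(dim(x)) == 4L) c(v, tr_seconds) else v
  RNifti::writeNifti(img, path)
  invisible(path)
}
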