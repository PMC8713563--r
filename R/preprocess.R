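#' Motion trace container
#'
#' Wraps a six-column motion-parameter matrix (three translations in mm,
#' three rotations in rad, one row per frame) together with its backward
#' differences and the framewise displacement used by the censoring rule.
#' By default framewise displacement is the Euclidean norm of the
#' frame-to-frame translation difference; rotations can optionally be
#' converted to mm on a 50 mm sphere and included.
#'
#' @param params Numeric matrix, frames x 6.
#' @param include_rotation Include rotation displacement (rad * radius) in
#'   the framewise displacement.
#' @param radius_mm Sphere radius for the rotation conversion.
#' @return Object of class `motion_trace` with elements `params`,
#'   `derivatives` (first differences, zero first row) and
#'   `framewise_displacement` (length frames - 1, non-negative).
#' @export
motion_trace <- function(params, include_rotation = FALSE, radius_mm = 50) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion parameters must have 6 columns")
  dpar <- rbind(0, diff(params))
  dtrans <- diff(params[, 1:3, drop = FALSE])
  fd <- sqrt(rowSums(dtrans^2))
  if (include_rotation) {
    drot <- diff(params[, 4:6, drop = FALSE]) * radius_mm
    fd <- sqrt(rowSums(dtrans^2) + rowSums(drot^2))
  }
  structure(list(params = params, derivatives = dpar,
                 framewise_displacement = fd),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames, mean FD %.3f mm, max FD %.3f mm\n",
              nrow(x$params), mean(x$framewise_displacement),
              max(x$framewise_displacement)))
  invisible(x)
}

# mean framewise displacement ("average motion per TR")
mean_motion <- function(motion) mean(motion$framewise_displacement)

#' Drop initial frames
#'
#' Removes the first `n_drop` frames from a volume and its motion trace
#' (steady-state magnetisation dummies).
#'
#' @param vol A [volume4d()].
#' @param motion A [motion_trace()] or raw 6-column matrix.
#' @param n_drop Number of initial frames to discard (default 4).
#' @return List with truncated `vol` and `motion`.
#' @export
drop_initial_frames <- function(vol, motion, n_drop = 4L) {
  stopifnot(inherits(vol, "volume4d"))
  if (inherits(motion, "motion_trace")) motion <- motion$params
  nt <- dim(vol$data)[4L]
  if (nrow(motion) != nt) stop("motion trace length does not match frames")
  if (n_drop >= nt) stop("cannot drop all frames")
  keep <- (n_drop + 1L):nt
  vol$data <- vol$data[, , , keep, drop = FALSE]
  list(vol = vol, motion = motion_trace(motion[keep, , drop = FALSE]))
}

#' Censor high-motion and outlier-laden frames
#'
#' A frame is censored when the Euclidean norm of its frame-to-frame
#' translation difference strictly exceeds `movement_mm` (the later frame of
#' the offending pair is removed), or when its fraction of outlier voxels
#' strictly exceeds `outlier_frac`. A voxel is an outlier in a frame when its
#' value deviates from the voxel's temporal median by more than three
#' MAD-based sigmas, so on clean Gaussian data the per-frame outlier
#' fraction stays near 0.3% and no frame is censored. Censored frames are
#' excluded from every subsequent regression and correlation.
#'
#' @param vol A [volume4d()] (after frame truncation).
#' @param motion A [motion_trace()] aligned to the frames of `vol`.
#' @param movement_mm Displacement threshold in mm (strict `>`).
#' @param outlier_frac Outlier-voxel fraction threshold (strict `>`).
#' @return `vol` with its `censored` set updated and attribute
#'   `censor_fraction`.
#' @export
censor_frames <- function(vol, motion, movement_mm = 0.3, outlier_frac = 0.10) {
  stopifnot(inherits(vol, "volume4d"), inherits(motion, "motion_trace"))
  nt <- dim(vol$data)[4L]
  if (nrow(motion$params) != nt)
    stop("motion trace length does not match number of frames")
  bad_move <- which(motion$framewise_displacement > movement_mm) + 1L

  d <- dim(vol$data)
  m <- matrix(vol$data, prod(d[1:3]), nt)
  med <- apply(m, 1L, stats::median)
  sigma <- apply(m, 1L, stats::mad)  # 1.4826 * MAD
  use <- sigma > 0
  out_frac <- colMeans(abs(m[use, , drop = FALSE] - med[use]) >
                         3 * sigma[use])
  bad_out <- which(out_frac > outlier_frac)

  vol$censored <- sort(unique(c(vol$censored, bad_move, bad_out)))
  attr(vol, "censor_fraction") <- length(vol$censored) / nt
  vol
}

#' Spatially smooth a 4D volume
#'
#' Applies mask-renormalised Gaussian smoothing (see [smooth_map()]) to
#' every frame; voxels outside the mask are left untouched, and no signal
#' bleeds across the mask boundary.
#'
#' @param vol A [volume4d()].
#' @param fwhm_mm Kernel FWHM in mm.
#' @param mask 3D logical array (default: all voxels).
#' @return Smoothed [volume4d()].
#' @export
smooth_gaussian <- function(vol, fwhm_mm, mask = NULL) {
  stopifnot(inherits(vol, "volume4d"), fwhm_mm > 0)
  v <- voxel_size(vol$affine)
  d <- dim(vol$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  for (t in seq_len(d[4L])) {
    fr <- vol$data[, , , t]
    sm <- smooth_map(fr, fwhm_mm, v, mask)
    fr[mask] <- sm[mask]
    vol$data[, , , t] <- fr
  }
  vol
}

# out-of-band frequency regressors: half-bin-spaced sin/cos below the low
# cutoff (captures slow drifts that fall between DFT bins) plus DFT-grid
# sin/cos above the high cutoff. Regressing these out inside the GLM
# band-passes the residuals while remaining exact under frame censoring.
band_stop_regressors <- function(n_frames, tr_seconds, band = c(0.01, 0.08)) {
  tt <- (seq_len(n_frames) - 1) * tr_seconds
  df <- 1 / (n_frames * tr_seconds)
  f_low <- seq(df / 2, band[1] - 1e-12, by = df / 2)
  f_all <- (1:floor(n_frames / 2)) * df
  f_high <- f_all[f_all > band[2] + 1e-12]
  fs <- c(f_low, f_high)
  if (!length(fs)) return(NULL)
  X <- do.call(cbind, lapply(fs, function(f)
    cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))))
  # drop numerically degenerate columns (e.g. sine at the Nyquist frequency)
  X[, apply(X, 2L, stats::sd) > 1e-8, drop = FALSE]
}

#' Motion and band-limiting nuisance regression
#'
#' Per voxel, ordinary least squares over the non-censored frames on an
#' intercept, the six motion parameters, their derivatives, and sine/cosine
#' regressors for all frequencies outside `band_hz`; returns the residuals.
#' Removing the out-of-band components inside the GLM implements the
#' band-pass filter in a way that remains valid when frames are censored.
#'
#' @param vol A [volume4d()] with censoring applied.
#' @param motion A [motion_trace()] aligned to the frames.
#' @param band_hz Retained frequency band in Hz.
#' @param mask 3D logical array restricting the voxels processed (default:
#'   all).
#' @return [volume4d()] of residuals (censored frames carry residuals too,
#'   but remain flagged and are ignored downstream).
#' @export
nuisance_glm <- function(vol, motion, band_hz = c(0.01, 0.08), mask = NULL) {
  stopifnot(inherits(vol, "volume4d"), inherits(motion, "motion_trace"))
  nt <- dim(vol$data)[4L]
  if (nrow(motion$params) != nt)
    stop("motion trace length does not match number of frames")
  X <- cbind(1, motion$params, motion$derivatives,
             band_stop_regressors(nt, vol$tr_seconds, band_hz))
  # motionless traces contribute all-zero columns; drop degenerate
  # regressors rather than reporting a spurious rank deficiency
  keep_col <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L, stats::sd) > 1e-12)
  X <- X[, keep_col, drop = FALSE]
  keep <- retained_frames(vol)
  qrx <- qr(X[keep, , drop = FALSE])
  if (qrx$rank < ncol(X))
    stop(sprintf("nuisance design rank-deficient (%d retained frames for %d regressors): subject flagged",
                 length(keep), ncol(X)))
  d <- dim(vol$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  Y <- mask_series(vol, mask)            # frames x voxels
  beta <- qr.coef(qrx, Y[keep, , drop = FALSE])
  res <- Y - X %*% beta
  set_mask_series(vol, mask, res)
}

#' Tissue-based nuisance regression
#'
#' Erodes the white-matter and ventricle masks by one voxel (6-connected,
#' single pass; falls back to the uneroded mask with a warning when erosion
#' empties it), then regresses the mean eroded-white-matter signal and the
#' first three principal-component time courses of the eroded ventricle
#' voxels (unit variance) out of every target voxel by OLS over the
#' non-censored frames.
#'
#' @param vol A [volume4d()].
#' @param wm_mask,vent_mask 3D logical tissue masks.
#' @param mask Target voxels to clean (default: all voxels outside the two
#'   tissue masks).
#' @param n_pcs Number of ventricle components (fewer are used, with a
#'   message, when the eroded mask has fewer voxels).
#' @return [volume4d()] of residuals.
#' @export
tissue_regression <- function(vol, wm_mask, vent_mask, mask = NULL, n_pcs = 3L) {
  stopifnot(inherits(vol, "volume4d"))
  ewm <- erode_mask(wm_mask)
  if (!any(ewm)) {
    warning("eroded white-matter mask empty; using uneroded mask")
    ewm <- wm_mask
  }
  evt <- erode_mask(vent_mask)
  if (!any(evt)) {
    warning("eroded ventricle mask empty; using uneroded mask")
    evt <- vent_mask
  }
  if (!any(ewm) || !any(evt)) stop("tissue masks must be nonempty")
  keep <- retained_frames(vol)
  wm_sig <- rowMeans(mask_series(vol, ewm))
  vser <- mask_series(vol, evt)
  k <- min(n_pcs, ncol(vser), length(keep) - 1L)
  if (k < n_pcs)
    message(sprintf("ventricle mask supports only %d component(s)", k))
  pcs <- stats::prcomp(vser[keep, , drop = FALSE], center = TRUE)$x[, seq_len(k), drop = FALSE]
  pcs <- scale(pcs)  # unit-variance time courses
  reg <- matrix(0, nrow(vser), k)
  reg[keep, ] <- pcs
  X <- cbind(1, wm_sig, reg)
  d <- dim(vol$data)
  if (is.null(mask)) mask <- !(wm_mask | vent_mask)
  Y <- mask_series(vol, mask)
  qrx <- qr(X[keep, , drop = FALSE])
  beta <- qr.coef(qrx, Y[keep, , drop = FALSE])
  beta[is.na(beta)] <- 0
  res <- Y - X %*% beta
  set_mask_series(vol, mask, res)
}

#' Full single-subject preprocessing
#'
#' Fixed stage order: drop the first four frames, censor by motion and
#' outlier fraction, smooth with a Gaussian kernel, regress motion +
#' out-of-band frequency nuisance, then tissue-based regression. The order
#' and all thresholds are recorded in the returned summary.
#'
#' @param vol Raw [volume4d()].
#' @param motion Raw motion-parameter matrix or [motion_trace()] aligned to
#'   the raw frames.
#' @param masks List with logical `gm`, `wm`, `vent` arrays.
#' @param n_drop Initial frames to discard.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @param movement_mm,outlier_frac Censoring thresholds.
#' @param band_hz Retained frequency band.
#' @return List: `vol` (preprocessed), `mean_motion_per_tr`,
#'   `censor_fraction`, `summary` (stage parameters).
#' @export
preprocess_subject <- function(vol, motion, masks, n_drop = 4L, fwhm_mm = 6,
                               movement_mm = 0.3, outlier_frac = 0.10,
                               band_hz = c(0.01, 0.08)) {
  tr0 <- drop_initial_frames(vol, motion, n_drop)
  vol <- tr0$vol; mot <- tr0$motion
  vol <- censor_frames(vol, mot, movement_mm, outlier_frac)
  # smoothing is restricted to gray matter: the white-matter and ventricle
  # voxels must stay unsmoothed so the tissue-based regressors are not
  # contaminated by gray-matter signal bleeding across the (desk-scale)
  # tissue boundaries
  vol <- smooth_gaussian(vol, fwhm_mm, masks$gm)
  brain <- masks$gm | masks$wm | masks$vent
  vol <- nuisance_glm(vol, mot, band_hz, brain)
  vol <- tissue_regression(vol, masks$wm, masks$vent, masks$gm)
  list(vol = vol,
       mean_motion_per_tr = mean_motion(mot),
       censor_fraction = attr(vol, "censor_fraction"),
       summary = list(order = c("truncate", "censor", "smooth",
                                "motion_band_glm", "tissue_regression"),
                      n_drop = n_drop, fwhm_mm = fwhm_mm,
                      movement_mm = movement_mm, outlier_frac = outlier_frac,
                      band_hz = band_hz))
}
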