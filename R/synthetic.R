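#' Design for a synthetic resting-state cohort
#'
#' Collects every parameter of the synthetic cohort generator: cohort size,
#' image grid, acquisition timing, the community structure of the
#' gray-matter mask, the coupling model that ties within-community
#' correlation to the exposure count, nuisance/noise levels, the motion
#' model, and covariate marginals. The defaults emulate a developmental
#' cohort: ages uniform on 8-21 years, 57.8% female, per-item exposure
#' rates set so that about 47.8% of subjects report at least one of the
#' nine binary items, maternal education negatively associated with the
#' exposure count, and a ~13% rate of a brain-injury exclusion flag.
#'
#' Within-community correlation for a subject with capped exposure count
#' `te` is `baseline + slope * te`, clipped to `[0, 0.95]`: the
#' somatomotor-like community uses `te_slope_main` for everyone (negative by
#' default, so connectivity falls with exposure), while the DMN-like
#' community uses `te_slope_male` / `te_slope_female` (opposite signs by
#' default). Coupling is realised through a per-community shared factor, so
#' the implied covariance is positive semi-definite for any coupling in
#' `[0, 1)`.
#'
#' @param n_subjects Number of subjects.
#' @param grid_shape Length-3 integer vector of voxels per axis.
#' @param voxel_size_mm Isotropic voxel edge in mm.
#' @param tr_seconds Repetition time in seconds.
#' @param n_trs Number of frames acquired (the first four are dropped during
#'   preprocessing; 124 frames at TR 3 s is a 6.2 min scan).
#' @param baseline_coupling Named vector with entries `somatomotor`, `dmn`,
#'   `background`: within-community correlation at exposure 0. Background
#'   gray matter is unstructured by default (coupling 0), so communities are
#'   the regions of elevated intrinsic connectivity.
#' @param te_slope_main Change of somatomotor-like coupling per exposure unit.
#' @param te_slope_male,te_slope_female Sex-specific DMN-like coupling slopes.
#' @param noise_sd SD of white observation noise added to unit-variance
#'   neural signal.
#' @param nuisance_mix Scale of the loadings with which the white-matter
#'   signal and three ventricle components are mixed into gray matter.
#' @param motion_gain Scale of the global signal artifact added on
#'   high-motion frames (per mm of framewise displacement).
#' @param motion_model List: `base_sd` (per-frame translation increment SD,
#'   mm), `spike_prob` (per-frame probability of a displacement spike),
#'   `spike_mm` (spike size, mm), `rot_sd` (rotation increment SD, rad),
#'   `high_motion_frac` (fraction of subjects with globally scaled motion),
#'   `high_motion_scale` (that scale).
#' @param female_frac Probability a subject is female.
#' @param exposure_class_frac Fraction of subjects in the exposure-prone
#'   latent class; traumatic events cluster within subjects, so the nine
#'   items are conditionally independent given the class rather than
#'   marginally independent. Subjects outside the class report no events.
#' @param item_rates Length-9 vector of per-item probabilities *within the
#'   exposure-prone class*; the default solves
#'   `exposure_class_frac * (1 - prod(1 - rates)) = 0.478` so that about
#'   47.8% of subjects report at least one event while two- and three-event
#'   subjects remain common enough to identify the exposure slope.
#' @param matedu_mean,matedu_sd,matedu_te_slope Maternal-education model
#'   (years): mean, SD, and change per raw exposure count.
#' @param injury_frac Probability of the brain-injury flag.
#' @param missing_te_frac Probability the nine items are missing as a block.
#' @param missing_matedu_frac Probability maternal education is missing.
#' @param clip_coupling If `FALSE`, out-of-range realised coupling is an
#'   error naming the subject instead of being clipped.
#' @param seed Integer seed; the seed and the design fully determine every
#'   generated output.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_subjects = 60L,
                       grid_shape = c(20L, 20L, 12L),
                       voxel_size_mm = 5,
                       tr_seconds = 3,
                       n_trs = 124L,
                       baseline_coupling = c(somatomotor = 0.55, dmn = 0.55,
                                             background = 0),
                       te_slope_main = -0.15,
                       te_slope_male = 0.12,
                       te_slope_female = -0.12,
                       noise_sd = 0.3,
                       nuisance_mix = 0.3,
                       motion_gain = 0.5,
                       motion_model = list(base_sd = 0.03, spike_prob = 0.04,
                                           spike_mm = 0.6, rot_sd = 5e-4,
                                           high_motion_frac = 0.12,
                                           high_motion_scale = 10),
                       female_frac = 0.578,
                       exposure_class_frac = 0.7,
                       item_rates = rep(1 - (1 - 0.478 / 0.7)^(1 / 9), 9L),
                       matedu_mean = 14,
                       matedu_sd = 2,
                       matedu_te_slope = -0.4,
                       injury_frac = 0.128,
                       missing_te_frac = 2 / 1395,
                       missing_matedu_frac = 7 / 1395,
                       clip_coupling = TRUE,
                       seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be at least 2")
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            voxel_size_mm > 0, tr_seconds > 0, n_trs >= 8L)
  probs <- c(female_frac, exposure_class_frac, item_rates, injury_frac,
             missing_te_frac, missing_matedu_frac)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("invalid probability parameter: all rates/fractions must lie in [0, 1]")
  if (length(item_rates) != 9L)
    stop("item_rates must have length 9 (one per questionnaire item)")
  cp <- baseline_coupling[c("somatomotor", "dmn", "background")]
  if (any(is.na(cp)) || any(cp < 0) || any(cp >= 1))
    stop("baseline_coupling must name somatomotor, dmn and background, each in [0, 1)")
  stopifnot(noise_sd > 0 || noise_sd == 0, nuisance_mix >= 0)
  structure(list(
    n_subjects = as.integer(n_subjects), grid_shape = as.integer(grid_shape),
    voxel_size_mm = voxel_size_mm, tr_seconds = tr_seconds,
    n_trs = as.integer(n_trs), baseline_coupling = cp,
    te_slope_main = te_slope_main, te_slope_male = te_slope_male,
    te_slope_female = te_slope_female, noise_sd = noise_sd,
    nuisance_mix = nuisance_mix, motion_gain = motion_gain,
    motion_model = motion_model,
    female_frac = female_frac, exposure_class_frac = exposure_class_frac,
    item_rates = item_rates,
    matedu_mean = matedu_mean, matedu_sd = matedu_sd,
    matedu_te_slope = matedu_te_slope, injury_frac = injury_frac,
    missing_te_frac = missing_te_frac,
    missing_matedu_frac = missing_matedu_frac,
    clip_coupling = isTRUE(clip_coupling), seed = as.integer(seed)
  ), class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design> %d subjects, grid %s, %d frames @ TR %.3g s, seed %d\n",
              x$n_subjects, paste(x$grid_shape, collapse = "x"), x$n_trs,
              x$tr_seconds, x$seed))
  cat(sprintf("  coupling: SM %.2f %+.2f/TE; DMN %.2f (M %+.2f, F %+.2f /TE); bg %.2f\n",
              x$baseline_coupling[["somatomotor"]], x$te_slope_main,
              x$baseline_coupling[["dmn"]], x$te_slope_male, x$te_slope_female,
              x$baseline_coupling[["background"]]))
  invisible(x)
}

# proportional box inside [lo, hi] given fractional bounds of the extent
.frac_box <- function(lo, hi, f1, f2) {
  w <- hi - lo
  seq.int(lo + round(f1 * w), lo + round(f2 * w))
}

#' Tissue masks, community map and reference parcellation for a grid
#'
#' Deterministic desk-scale anatomy: a central gray-matter box containing a
#' somatomotor-like community, a DMN-like community and background gray
#' matter; a ventricle block carved out of the gray-matter box; white matter
#' filling the remainder of the grid. The reference parcellation carries
#' seven labels: label 2 covers the somatomotor-like community, label 7 the
#' DMN-like community, and background gray matter is split into slabs
#' carrying labels 1, 3, 4, 5, 6 (0 = unlabeled, as outside gray matter).
#'
#' @param grid_shape Length-3 integer vector.
#' @return List with logical arrays `gm`, `wm`, `vent`, integer array
#'   `community` (0 none, 1 somatomotor-like, 2 DMN-like, 3 background) and
#'   integer array `parcellation` (labels 0-7).
#' @export
default_anatomy <- function(grid_shape) {
  d <- as.integer(grid_shape)
  stopifnot(length(d) == 3L, all(d >= 6L))
  m <- floor(0.15 * d)
  xr <- (m[1] + 1):(d[1] - m[1]); yr <- (m[2] + 1):(d[2] - m[2])
  zr <- (m[3] + 1):(d[3] - m[3])
  gm_box <- array(FALSE, d); gm_box[xr, yr, zr] <- TRUE

  xlo <- min(xr); xhi <- max(xr); ylo <- min(yr); yhi <- max(yr)
  zlo <- min(zr); zhi <- max(zr)
  sm_x <- .frac_box(xlo, xhi, 0.05, 0.55); sm_y <- .frac_box(ylo, yhi, 0.05, 0.55)
  sm_z <- .frac_box(zlo, zhi, 0.55, 0.95)
  dmn_x <- .frac_box(xlo, xhi, 0.45, 0.95); dmn_y <- .frac_box(ylo, yhi, 0.45, 0.95)
  dmn_z <- .frac_box(zlo, zhi, 0.05, 0.45)
  vent_x <- .frac_box(xlo, xhi, 0.10, 0.35); vent_y <- .frac_box(ylo, yhi, 0.65, 0.95)
  vent_z <- .frac_box(zlo, zhi, 0.25, 0.70)

  vent <- array(FALSE, d); vent[vent_x, vent_y, vent_z] <- TRUE
  gm <- gm_box & !vent
  wm <- !gm_box
  community <- array(0L, d)
  community[gm] <- 3L
  sm <- array(FALSE, d); sm[sm_x, sm_y, sm_z] <- TRUE
  dmn <- array(FALSE, d); dmn[dmn_x, dmn_y, dmn_z] <- TRUE
  stopifnot(!any(sm & vent), !any(dmn & vent), !any(sm & dmn))
  community[sm] <- 1L
  community[dmn] <- 2L

  parc <- array(0L, d)
  parc[community == 1L] <- 2L   # somatomotor label in 7-network convention
  parc[community == 2L] <- 7L   # default-mode label
  bg_idx <- which(community == 3L)
  if (length(bg_idx)) {
    yy <- lin_to_coord(bg_idx, d)[, 2L]
    slab <- cut(yy, breaks = 5L, labels = FALSE)
    parc[bg_idx] <- c(1L, 3L, 4L, 5L, 6L)[slab]
  }
  list(gm = gm, wm = wm, vent = vent, community = community,
       parcellation = parc)
}

#' Simulate subject covariates
#'
#' Draws ages uniformly on 8-21 years, sex with the configured female
#' fraction, nine independent binary exposure items, maternal education in
#' years negatively related to the raw item sum, a brain-injury flag, and
#' (rarely) block-missing items or missing maternal education, so that the
#' downstream quality-control gates are exercised.
#'
#' @param design A [sim_design()].
#' @return A data.frame with one row per subject: `subject_id`, `sex`
#'   (factor female/male, female first), `age`, `maternal_education`,
#'   `item1`..`item9` (0/1 or NA as a block), `brain_injury` (logical).
#' @export
simulate_covariates <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  n <- design$n_subjects
  set.seed(design$seed)
  sex <- factor(ifelse(stats::runif(n) < design$female_frac, "female", "male"),
                levels = c("female", "male"))
  age <- stats::runif(n, 8, 21)
  prone <- stats::runif(n) < design$exposure_class_frac
  items <- vapply(design$item_rates,
                  function(p) as.integer(stats::runif(n) < p),
                  integer(n))
  if (is.null(dim(items))) items <- matrix(items, nrow = n)
  items[!prone, ] <- 0L
  te_raw <- rowSums(items)
  medu <- design$matedu_mean + design$matedu_te_slope * te_raw +
    stats::rnorm(n, 0, design$matedu_sd)
  medu <- pmin(pmax(round(medu), 6), 20)
  injury <- stats::runif(n) < design$injury_frac
  miss_te <- stats::runif(n) < design$missing_te_frac
  miss_me <- stats::runif(n) < design$missing_matedu_frac
  items[miss_te, ] <- NA_integer_
  medu[miss_me] <- NA_real_
  out <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    sex = sex, age = age, maternal_education = medu,
    stringsAsFactors = FALSE
  )
  colnames(items) <- paste0("item", 1:9)
  out <- cbind(out, as.data.frame(items))
  out$brain_injury <- injury
  out
}

# realised coupling for one subject; clips to [0, 0.95] or errors
.realised_coupling <- function(design, te, male, subject_id) {
  rho <- c(
    somatomotor = design$baseline_coupling[["somatomotor"]] +
      design$te_slope_main * te,
    dmn = design$baseline_coupling[["dmn"]] +
      (if (male) design$te_slope_male else design$te_slope_female) * te,
    background = design$baseline_coupling[["background"]]
  )
  clipped <- sum(rho < 0 | rho > 0.95)
  if (clipped > 0 && !design$clip_coupling)
    stop(sprintf("coupling out of [0, 0.95] for subject %s (values: %s): covariance would not be PSD",
                 subject_id, paste(sprintf("%.3f", rho), collapse = ", ")))
  list(rho = pmin(pmax(rho, 0), 0.95), clipped = clipped)
}

# band-limited smooth nuisance source: sum of in-band sinusoids, unit SD
.nuisance_source <- function(tt, n_comp = 4L, f_range = c(0.02, 0.07)) {
  f <- stats::runif(n_comp, f_range[1], f_range[2])
  ph <- stats::runif(n_comp, 0, 2 * pi)
  a <- stats::runif(n_comp, 0.5, 1.5)
  s <- colSums(a * sin(outer(2 * pi * f, tt) + ph))
  s / stats::sd(s)
}

#' Simulate the imaging arm of a synthetic cohort
#'
#' For each subject draws BOLD-like time series from the block coupling
#' model (a shared factor per voxel community, so within-community
#' correlation equals the realised coupling exactly in the generating
#' model), adds band-limited white-matter and ventricle nuisance signals
#' that are linearly mixed into gray matter, white observation noise, a
#' motion-locked global artifact, and a six-parameter motion trace whose
#' displacement spikes make a configurable fraction of frames censorable.
#'
#' @param design A [sim_design()].
#' @param subjects Covariate table from [simulate_covariates()].
#' @return An object of class `synthetic_cohort`: list with `design`,
#'   `subjects`, `images` (list of [volume4d()]), `motion` (list of n_trs x 6
#'   matrices), `masks` (gm/wm/vent), `community`, `parcellation`, and
#'   `truth` (per-voxel generating slope maps, per-subject realised coupling,
#'   clip count).
#' @export
simulate_images <- function(design, subjects) {
  stopifnot(inherits(design, "sim_design"), is.data.frame(subjects))
  anat <- default_anatomy(design$grid_shape)
  d <- design$grid_shape
  nt <- design$n_trs
  tt <- (seq_len(nt) - 1) * design$tr_seconds
  affine <- make_affine(design$voxel_size_mm)
  n <- nrow(subjects)
  mm <- design$motion_model

  items <- as.matrix(subjects[paste0("item", 1:9)])
  te_raw <- rowSums(items)
  te <- pmin(te_raw, 3L)
  te[is.na(te)] <- 0L  # missing items: generate as unexposed; QC will exclude

  idx_sm <- which(anat$community == 1L)
  idx_dmn <- which(anat$community == 2L)
  idx_bg <- which(anat$community == 3L)
  idx_gm <- which(anat$gm)
  idx_wm <- which(anat$wm)
  idx_vent <- which(anat$vent)
  n_gm <- length(idx_gm)

  images <- vector("list", n)
  motion <- vector("list", n)
  coupling <- data.frame(subject_id = subjects$subject_id,
                         rho_somatomotor = NA_real_, rho_dmn = NA_real_,
                         rho_background = NA_real_)
  n_clipped <- 0L

  set.seed(design$seed + 1L)
  high_motion <- stats::runif(n) < mm$high_motion_frac

  for (s in seq_len(n)) {
    rc <- .realised_coupling(design, te[s], subjects$sex[s] == "male",
                             subjects$subject_id[s])
    n_clipped <- n_clipped + rc$clipped
    rho <- rc$rho
    coupling[s, 2:4] <- rho

    vol <- matrix(0, nt, prod(d))
    for (cm in 1:3) {
      idx <- list(idx_sm, idx_dmn, idx_bg)[[cm]]
      r <- rho[[cm]]
      g <- stats::rnorm(nt)
      e <- matrix(stats::rnorm(nt * length(idx)), nt)
      vol[, idx] <- sqrt(r) * g + sqrt(1 - r) * e
    }

    # nuisance sources: WM mean signal and three ventricle components
    w <- .nuisance_source(tt)
    v <- vapply(1:3, function(k) .nuisance_source(tt), numeric(nt))
    if (design$nuisance_mix > 0) {
      load <- matrix(design$nuisance_mix * stats::runif(n_gm * 4L, 0.5, 1.5),
                     n_gm, 4L)
      vol[, idx_gm] <- vol[, idx_gm] +
        tcrossprod(cbind(w, v), load)
    }
    vol[, idx_wm] <- w + matrix(stats::rnorm(nt * length(idx_wm), 0, 0.3), nt)
    amix <- matrix(stats::rnorm(length(idx_vent) * 3L), ncol = 3L) %*%
      diag(c(1, 0.6, 0.35))
    vol[, idx_vent] <- v %*% t(amix) +
      matrix(stats::rnorm(nt * length(idx_vent), 0, 0.1), nt)

    if (design$noise_sd > 0)
      vol <- vol + matrix(stats::rnorm(nt * prod(d), 0, design$noise_sd), nt)

    # motion trace: random-walk translations/rotations with spikes
    scale <- if (high_motion[s]) mm$high_motion_scale else 1
    inc <- matrix(stats::rnorm(nt * 3L, 0, mm$base_sd * scale), nt)
    spike <- stats::runif(nt) < mm$spike_prob
    spike[1L] <- FALSE
    if (any(spike)) {
      dir <- matrix(stats::rnorm(sum(spike) * 3L), ncol = 3L)
      dir <- dir / sqrt(rowSums(dir^2))
      inc[spike, ] <- inc[spike, , drop = FALSE] + mm$spike_mm * dir
    }
    trans <- apply(inc, 2L, cumsum)
    rot <- apply(matrix(stats::rnorm(nt * 3L, 0, mm$rot_sd * scale), nt),
                 2L, cumsum)
    pars <- cbind(trans, rot)

    # motion-locked artifact shared across voxels
    if (design$motion_gain > 0) {
      fd <- c(0, sqrt(rowSums(diff(trans)^2)))
      u <- stats::rnorm(prod(d), 0, 1)
      vol <- vol + (design$motion_gain * fd) %o% u
    }

    images[[s]] <- volume4d(array(t(1000 + 20 * vol), c(d, nt)), affine,
                            design$tr_seconds)
    motion[[s]] <- pars
  }

  slope_main <- array(0, d); slope_main[idx_sm] <- design$te_slope_main
  slope_male <- array(0, d); slope_male[idx_dmn] <- design$te_slope_male
  slope_female <- array(0, d); slope_female[idx_dmn] <- design$te_slope_female

  structure(list(
    design = design, subjects = subjects, images = images, motion = motion,
    masks = list(gm = anat$gm, wm = anat$wm, vent = anat$vent),
    community = anat$community, parcellation = anat$parcellation,
    truth = list(slope_main = slope_main, slope_male = slope_male,
                 slope_female = slope_female, coupling = coupling,
                 n_clipped = n_clipped)
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, grid %s, %d gray-matter voxels\n",
              length(x$images), paste(x$design$grid_shape, collapse = "x"),
              sum(x$masks$gm)))
  if (x$truth$n_clipped > 0)
    cat(sprintf("  %d coupling value(s) clipped to [0, 0.95]\n", x$truth$n_clipped))
  invisible(x)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [simulate_covariates()] followed by
#' [simulate_images()].
#'
#' @param design A [sim_design()].
#' @return A `synthetic_cohort`.
#' @export
simulate_cohort <- function(design) {
  simulate_images(design, simulate_covariates(design))
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject 4D BOLD NIfTI files and whitespace-delimited motion
#' parameter files (one row per frame: three translations in mm, three
#' rotations in rad), the tissue masks and the 7-label reference
#' parcellation as 3D NIfTI, and the covariate table as a tab-separated
#' file with a header row.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aff <- cohort$images[[1]]$affine
  for (s in seq_along(cohort$images)) {
    id <- cohort$subjects$subject_id[s]
    write_nifti(cohort$images[[s]], file.path(dir, paste0(id, "_bold.nii.gz")))
    utils::write.table(format(cohort$motion[[s]], digits = 10),
                       file.path(dir, paste0(id, "_motion.txt")),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  for (nm in names(cohort$masks))
    write_nifti(cohort$masks[[nm]], file.path(dir, paste0(nm, ".nii.gz")),
                affine = aff)
  write_nifti(cohort$parcellation, file.path(dir, "parcellation.nii.gz"),
              affine = aff)
  utils::write.table(cohort$subjects, file.path(dir, "covariates.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
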