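# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# small, quiet design: no motion spikes, no high-motion subjects, optional
# nuisance/noise, suitable for fast deterministic image tests
quiet_design <- function(n_subjects = 4, grid_shape = c(14, 14, 8), seed = 1,
                         noise_sd = 0.4, nuisance_mix = 0, motion_gain = 0,
                         ...) {
  sim_design(
    n_subjects = n_subjects, grid_shape = grid_shape, seed = seed,
    noise_sd = noise_sd, nuisance_mix = nuisance_mix,
    motion_gain = motion_gain,
    motion_model = list(base_sd = 0.01, spike_prob = 0, spike_mm = 0,
                        rot_sd = 1e-4, high_motion_frac = 0,
                        high_motion_scale = 1),
    injury_frac = 0, missing_te_frac = 0, missing_matedu_frac = 0,
    ...
  )
}

# a volume4d holding given frames x voxels series over the full grid
vol_from_series <- function(series, dims, tr = 3, voxel_mm = 3) {
  stopifnot(ncol(series) == prod(dims))
  volume4d(array(t(series), c(dims, nrow(series))), make_affine(voxel_mm), tr)
}

# subject covariate table with exact fields for design-matrix tests
fake_subjects <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    te_coded = sample(0:3, n, replace = TRUE),
    sex = factor(sample(c("female", "male"), n, replace = TRUE),
                 levels = c("female", "male")),
    age = runif(n, 8, 21),
    maternal_education = round(runif(n, 8, 18)),
    stringsAsFactors = FALSE
  )
}

# direct-space brute-force mask-renormalised 3D Gaussian convolution: an
# independent oracle for the separable smoother, computing conv(x*m)/conv(m)
# with an explicit full 3D kernel
brute_force_smooth <- function(x, fwhm_mm, voxel_mm, mask = NULL) {
  d <- dim(x)
  if (is.null(mask)) mask <- array(TRUE, d)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, ceiling(3.5 * sig))
  off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  w <- exp(-rowSums(off^2) / (2 * sig^2))
  w <- w / sum(w)
  xm <- ifelse(mask, x, 0)
  mm <- array(as.numeric(mask), d)
  num <- array(0, d); den <- array(0, d)
  shift <- function(a, o) {
    sh <- array(0, d)
    sx <- pmax(1, 1 - o[1]):pmin(d[1], d[1] - o[1])
    sy <- pmax(1, 1 - o[2]):pmin(d[2], d[2] - o[2])
    sz <- pmax(1, 1 - o[3]):pmin(d[3], d[3] - o[3])
    sh[sx + o[1], sy + o[2], sz + o[3]] <- a[sx, sy, sz]
    sh
  }
  for (m in seq_len(nrow(off))) {
    num <- num + w[m] * shift(xm, off[m, ])
    den <- den + w[m] * shift(mm, off[m, ])
  }
  out <- array(NA_real_, d)
  out[mask] <- num[mask] / den[mask]
  out
}

# alpha-map stack with a planted linear exposure effect, for GLM-level tests
planted_alpha_stack <- function(subjects, mask, slope_map, noise_sd = 1,
                                male_map = NULL, seed = 1) {
  set.seed(seed)
  n <- nrow(subjects)
  V <- sum(mask)
  sl <- slope_map[mask]
  base <- 3
  male <- as.numeric(subjects$sex == "male")
  Y <- matrix(rnorm(n * V, 0, noise_sd), n, V) + base
  Y <- Y + outer(subjects$te_coded, sl)
  if (!is.null(male_map))
    Y <- Y + outer(subjects$te_coded * male, male_map[mask])
  Y
}
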