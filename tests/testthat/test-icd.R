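# Intrinsic connectivity distribution: survival curves, model fitting,
# subject-level maps

tau_grid <- seq(0.01, 0.99, by = 0.01)

test_that("survival curves are valid and match hand-computed toy correlations", {
  # perfect correlation with everything: survival identically 1
  s1 <- survival_curve(rep(1, 50))
  expect_true(all(s1$survival == 1))

  # three-voxel toy: correlations computed independently with cor() on
  # printed series, then survival built from {0.5ish positive, negative}
  a <- c(1, 2, 3, 4, 5, 6)
  b <- c(2, 1, 4, 3, 6, 5)
  cc <- c(6, 5, 4, 3, 2, 1)
  r_ab <- cor(a, b)   # positive
  r_ac <- cor(a, cc)  # -1
  sc <- survival_curve(c(r_ab, r_ac))
  expect_equal(sc$n_positive, 1L)
  expect_true(all(sc$survival[sc$tau < r_ab] == 1))
  expect_true(all(sc$survival[sc$tau >= r_ab] == 0))

  # generic validity: non-increasing, within [0,1]
  set.seed(2)
  s3 <- survival_curve(runif(500, -1, 1))
  expect_true(all(diff(s3$survival) <= 0))
  expect_true(all(s3$survival >= 0 & s3$survival <= 1))
})

test_that("an independent voxel's survival vanishes beyond the null sampling scale", {
  # null-correlation oracle: with T frames, sample correlations are
  # approximately N(0, 1/sqrt(T)); survival past 3/sqrt(T) is negligible
  set.seed(4)
  T <- 400
  x <- rnorm(T)
  others <- matrix(rnorm(T * 300), T)
  r <- as.vector(cor(x, others))
  sc <- survival_curve(r)
  expect_lt(max(sc$survival[sc$tau > 3 / sqrt(T)]), 0.02)
})

test_that("fitting recovers exact model curves to high precision and the grid oracle confirms the optimum", {
  set.seed(1)
  for (i in 1:20) {
    al <- runif(1, 0.5, 4); be <- runif(1, 0.5, 3)
    cv <- survival_curve(numeric(0))
    cv$survival <- exp(-(al * tau_grid)^be)
    cv$n_positive <- 1000L
    ft <- fit_icd(cv)
    expect_true(ft$converged)
    expect_lt(abs(ft$alpha - al) / al, 1e-6)
    expect_lt(abs(ft$beta - be) / be, 1e-6)
    expect_lt(ft$rss, 1e-12)
  }
  # independent grid-search oracle cannot beat the fitted optimum
  cv <- survival_curve(numeric(0))
  cv$survival <- exp(-(2 * tau_grid)^1.5) + 0.02 * sin(8 * tau_grid)
  cv$survival <- pmin(pmax(cv$survival, 0), 1)
  cv$n_positive <- 1000L
  ft <- fit_icd(cv)
  gs <- icd_grid_search(cv)
  expect_lte(ft$rss, gs$rss + 1e-10)
})

test_that("degenerate curves fail explicitly instead of returning silent zeros", {
  flat <- survival_curve(rep(1, 100))     # survival identically 1
  ft <- fit_icd(flat)
  expect_false(ft$converged)
  expect_true(is.na(ft$alpha))
  empty <- survival_curve(rep(-0.5, 30))  # no positive correlations
  expect_false(fit_icd(empty)$converged)
})

test_that("stochastically dominated curves never get a smaller alpha", {
  # dominated curve = dominating curve times a second decay factor
  # (pointwise strictly smaller survival)
  set.seed(10)
  for (i in 1:25) {
    a1 <- runif(1, 0.5, 3); b1 <- runif(1, 0.7, 2.5)
    a2 <- runif(1, 0.3, 2); b2 <- runif(1, 0.7, 2.5)
    hi <- exp(-(a1 * tau_grid)^b1)
    lo <- hi * exp(-(a2 * tau_grid)^b2)
    mk <- function(s) {
      cv <- survival_curve(numeric(0))
      cv$survival <- s; cv$n_positive <- 1000L
      cv
    }
    f_hi <- fit_icd(mk(hi)); f_lo <- fit_icd(mk(lo))
    expect_true(f_hi$converged && f_lo$converged)
    expect_gte(f_lo$alpha, f_hi$alpha)
  }
})

test_that("icd_fit behaves like a fitted-model object", {
  cv <- survival_curve(numeric(0))
  cv$survival <- exp(-(1.4 * tau_grid)^1.1)
  cv$n_positive <- 500L
  ft <- fit_icd(cv)
  expect_named(coef(ft), c("alpha", "beta"))
  expect_equal(predict(ft), ft$fitted)
  expect_equal(predict(ft, newdata = c(0.2, 0.5)),
               exp(-(ft$alpha * c(0.2, 0.5))^ft$beta))
  expect_equal(residuals(ft), cv$survival - ft$fitted)
  expect_output(print(ft), "alpha")
})

make_block_subject <- function(seed, coupling = 0.5, grid = c(12, 12, 8)) {
  des <- quiet_design(n_subjects = 2, grid_shape = grid, seed = seed,
                      noise_sd = 0.4,
                      baseline_coupling = c(somatomotor = coupling, dmn = 0.5,
                                            background = 0),
                      te_slope_main = 0, te_slope_male = 0,
                      te_slope_female = 0)
  co <- simulate_cohort(des)
  list(vol = co$images[[1]], gm = co$masks$gm, community = co$community)
}

test_that("voxel_correlations matches the map produced by icd_subject", {
  bs <- make_block_subject(31)
  vx <- which(bs$gm)[10]
  cv <- voxel_correlations(bs$vol, bs$gm, vx)
  ft <- fit_icd(cv)
  maps <- icd_subject(bs$vol, bs$gm)
  expect_equal(maps$alpha[vx], ft$alpha, tolerance = 1e-8)
  expect_equal(maps$n_positive[vx], cv$n_positive)
})

test_that("high-coupling community voxels get smaller alpha than background", {
  bs <- make_block_subject(7)
  maps <- icd_subject(bs$vol, bs$gm)
  expect_lt(mean(maps$alpha[bs$community == 1], na.rm = TRUE),
            mean(maps$alpha[bs$community == 3], na.rm = TRUE))
})

test_that("community alpha decreases when coupling rises from 0.3 to 0.6", {
  for (seed in c(3, 4)) {
    lo <- make_block_subject(seed, coupling = 0.3)
    hi <- make_block_subject(seed, coupling = 0.6)
    a_lo <- mean(icd_subject(lo$vol, lo$gm)$alpha[lo$community == 1],
                 na.rm = TRUE)
    a_hi <- mean(icd_subject(hi$vol, hi$gm)$alpha[hi$community == 1],
                 na.rm = TRUE)
    expect_lt(a_hi, a_lo)
  }
})

test_that("maps are invariant to chunk size and per-voxel rescaling", {
  bs <- make_block_subject(12, grid = c(10, 10, 6))
  m1 <- icd_subject(bs$vol, bs$gm, chunk_size = 17L)
  m2 <- icd_subject(bs$vol, bs$gm, chunk_size = 512L)
  expect_identical(m1$alpha, m2$alpha)

  # correlation is scale-free: rescaling every voxel's series changes nothing
  d <- dim(bs$vol$data)
  scl <- runif(prod(d[1:3]), 0.5, 3)
  v2 <- bs$vol
  v2$data <- array(matrix(v2$data, prod(d[1:3])) * scl, d)
  m3 <- icd_subject(v2, bs$gm)
  expect_equal(m3$alpha, m1$alpha, tolerance = 1e-8)
})

test_that("ICD ranks voxels like a fixed-threshold degree statistic", {
  bs <- make_block_subject(9)
  maps <- icd_subject(bs$vol, bs$gm)
  keep <- retained_frames(bs$vol)
  Y <- t(matrix(bs$vol$data, prod(dim(bs$vol$data)[1:3]),
                dim(bs$vol$data)[4]))[keep, which(bs$gm)]
  C <- cor(Y)
  diag(C) <- NA
  degree <- colSums(C > 0.25, na.rm = TRUE)
  al <- maps$alpha[bs$gm]
  expect_gt(cor(-al, degree, method = "spearman", use = "complete.obs"), 0.8)
})

test_that("zero-variance voxels are flagged and excessive failure aborts", {
  bs <- make_block_subject(15, grid = c(10, 10, 6))
  d <- dim(bs$vol$data)
  flat <- bs$vol
  m <- matrix(flat$data, prod(d[1:3]), d[4])
  vx <- which(bs$gm)[1]
  m[vx, ] <- 5  # constant series
  flat$data <- array(m, d)
  maps <- icd_subject(flat, bs$gm)
  expect_true(is.na(maps$alpha[vx]))
  expect_true(maps$fail[vx])
  expect_equal(maps$n_fail, 1L)

  res <- voxel_correlations(flat, bs$gm, vx)
  expect_true(is.na(res[1]))
  expect_equal(attr(res, "reason"), "zero-variance voxel")

  m[, ] <- 1  # everything constant: all fits fail -> abort
  flat$data <- array(m, d)
  expect_error(icd_subject(flat, bs$gm), "failed")
})

test_that("parameter-map smoothing preserves constants, conserves a delta, matches the oracle", {
  an <- default_anatomy(c(12, 12, 8))
  maps <- structure(list(alpha = array(NA_real_, dim(an$gm)),
                         beta = array(NA_real_, dim(an$gm)),
                         gm_mask = an$gm, affine = make_affine(3),
                         fail = array(FALSE, dim(an$gm)), n_fail = 0L),
                    class = "icd_maps")
  maps$alpha[an$gm] <- 2.5
  maps$beta[an$gm] <- 1.5
  sm <- smooth_parameter_map(maps, 4)
  expect_equal(sm$alpha[an$gm], rep(2.5, sum(an$gm)), tolerance = 1e-12)

  # delta anomaly: total mass over the mask is approximately preserved
  # (mask renormalisation redistributes a little mass near the gray-matter
  # boundary, so conservation is not exact for an arbitrary in-mask voxel)
  maps$alpha[an$gm] <- 0
  ctr <- which(an$gm & array(TRUE, dim(an$gm)))[round(sum(an$gm) / 2)]
  maps$alpha[ctr] <- 1
  sm2 <- smooth_parameter_map(maps, 4)
  expect_equal(sum(sm2$alpha[an$gm]), 1, tolerance = 0.15)

  # against the direct-space convolution oracle on a full-mask grid
  full <- structure(list(alpha = array(rnorm(8^3), c(8, 8, 8)),
                         beta = array(1, c(8, 8, 8)),
                         gm_mask = array(TRUE, c(8, 8, 8)),
                         affine = make_affine(3),
                         fail = array(FALSE, c(8, 8, 8)), n_fail = 0L),
                    class = "icd_maps")
  sm3 <- smooth_parameter_map(full, 4)
  oracle <- brute_force_smooth(full$alpha, 4, 3)
  expect_lt(max(abs(sm3$alpha - oracle)), 1e-10)
})
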