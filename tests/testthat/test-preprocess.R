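# Frame censoring, masked smoothing, nuisance GLM, tissue regression

dims8 <- c(8, 8, 6)

test_that("frame censoring applies the strict 0.3 mm point-to-point rule", {
  nt <- 10
  trans <- matrix(0, nt, 3)
  trans[2:nt, 1] <- cumsum(c(0.3, 0.4, rep(0, nt - 3)))  # jumps 0.3 then 0.4
  mot <- motion_trace(cbind(trans, matrix(0, nt, 3)))
  set.seed(1)
  vol <- vol_from_series(matrix(rnorm(nt * prod(dims8)), nt), dims8)
  out <- censor_frames(vol, mot)
  # the 0.4 mm transition censors its later frame; the 0.3 mm one does not
  expect_equal(out$censored, 3L)
  expect_equal(attr(out, "censor_fraction"), 1 / nt)
})

test_that("clean Gaussian data is never outlier-censored; degenerate censoring is total", {
  set.seed(42)
  nt <- 60
  vol <- vol_from_series(matrix(rnorm(nt * prod(dims8)), nt), dims8)
  mot <- motion_trace(matrix(0, nt, 6))
  out <- censor_frames(vol, mot)
  expect_length(out$censored, 0L)

  # every transition above threshold: censor_fraction hits (nt-1)/nt
  big <- motion_trace(cbind(cumsum(rep(1, nt)), matrix(0, nt, 5)))
  out2 <- censor_frames(vol, big)
  expect_equal(attr(out2, "censor_fraction"), (nt - 1) / nt)
  expect_error(censor_frames(vol, motion_trace(matrix(0, nt + 1, 6))),
               "match")
})

test_that("masked smoothing conserves a delta, fixes constants, and matches the brute-force oracle", {
  d <- c(14, 14, 14)
  mask <- array(TRUE, d)
  # central delta: the kernel support stays a full radius away from the
  # grid edge, so the renormalisation is inert and mass is conserved exactly
  delta <- array(0, d); delta[7, 7, 7] <- 1
  sm <- smooth_map(delta, 6, 3, mask)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  d <- c(8, 8, 8)
  mask <- array(TRUE, d)
  # constant in-mask image is invariant even with an irregular mask
  maskc <- array(runif(prod(d)) > 0.3, d)
  const <- array(NA_real_, d); const[maskc] <- 7
  smc <- smooth_map(const, 6, 3, maskc)
  expect_equal(smc[maskc], rep(7, sum(maskc)), tolerance = 1e-12)
  expect_true(all(is.na(smc[!maskc])))
  # separable implementation equals direct-space 3D convolution
  set.seed(3)
  x <- array(rnorm(prod(d)), d)
  expect_lt(max(abs(smooth_map(x, 4, 3, mask) - brute_force_smooth(x, 4, 3))),
            1e-10)
})

test_that("smoothed white noise has the kernel's effective FWHM", {
  set.seed(11)
  d <- c(24, 24, 16)
  x <- array(rnorm(prod(d)), d)
  sm <- smooth_map(x, 6, 3, array(TRUE, d))
  inner <- sm[3:22, 3:22, 3:14]
  # spatial autocorrelation of Gaussian-smoothed white noise at lag h mm is
  # exp(-h^2 / (4 sigma_eff^2)); invert at the 3 mm lag
  c1 <- cor(as.vector(inner[-1, , ]), as.vector(inner[-20, , ]))
  sigma_eff <- sqrt(-9 / (4 * log(c1)))
  fwhm_eff <- 2 * sqrt(2 * log(2)) * sigma_eff
  # white noise carries no intrinsic smoothness, so the effective width
  # should reproduce the nominal kernel width (up to discretisation)
  expect_lt(abs(fwhm_eff - 6) / 6, 0.15)
  # and the brute-force oracle yields the identical smoothed field
  expect_lt(max(abs(sm - brute_force_smooth(x, 6, 3))), 1e-10)
})

test_that("band-limiting GLM keeps in-band signal and removes drift and motion", {
  nt <- 120
  tt <- (0:(nt - 1)) * 3
  mot <- motion_trace(matrix(0, nt, 6))
  inband <- sin(2 * pi * 0.05 * tt + 0.4)
  drift <- sin(2 * pi * 0.005 * tt + 1.1)
  d <- c(4, 4, 2)
  series <- matrix(0, nt, prod(d))
  series[, 1] <- inband
  series[, 2] <- drift
  vol <- vol_from_series(series, d)
  out <- nuisance_glm(vol, mot)
  res <- t(matrix(out$data, prod(d), nt))
  amp <- function(x) sqrt(mean(x^2))
  # FFT-oracle targets: >=95% of in-band amplitude kept, <=5% of drift kept
  expect_gte(amp(res[, 1]) / amp(inband - mean(inband)), 0.95)
  expect_lte(amp(res[, 2]) / amp(drift - mean(drift)), 0.05)
  # residuals have zero mean (intercept in the model)
  expect_lt(max(abs(colMeans(res))), 1e-10)

  # a series equal to a motion regressor is annihilated
  set.seed(5)
  pars <- matrix(cumsum(rnorm(nt * 6, 0, 0.02)), nt)
  mot2 <- motion_trace(pars)
  series2 <- matrix(rnorm(nt * prod(d)), nt)
  series2[, 3] <- pars[, 2]
  out2 <- nuisance_glm(vol_from_series(series2, d), mot2)
  expect_lt(max(abs(out2$data[, , , ][rep(c(FALSE, FALSE, TRUE,
                                            rep(FALSE, prod(d) - 3)), nt)])),
            1e-8)
})

test_that("rank-deficient nuisance designs are flagged, not silently fit", {
  # heavy censoring leaves fewer retained frames than regressors
  nt <- 120
  d <- c(4, 4, 2)
  set.seed(30)
  vol <- vol_from_series(matrix(rnorm(nt * prod(d)), nt), d)
  vol$censored <- 1:80
  mot <- motion_trace(matrix(rnorm(nt * 6, 0, 0.01), nt))
  expect_error(nuisance_glm(vol, mot), "rank")
})

test_that("tissue regression removes planted WM/ventricle signal and keeps orthogonal signal", {
  set.seed(7)
  an <- default_anatomy(c(14, 14, 8))
  d <- dim(an$gm)
  nt <- 100
  V <- prod(d)
  series <- matrix(rnorm(nt * V, 0, 1e-6), nt)  # tiny floor avoids zero sd

  # case 1: gray matter IS the broadcast WM mean -> residual ~ 0
  w <- rnorm(nt)
  series[, which(an$wm)] <- w + matrix(rnorm(nt * sum(an$wm), 0, 0.05), nt)
  series[, which(an$gm)] <- w
  v3 <- matrix(rnorm(nt * 3), nt)
  series[, which(an$vent)] <- v3 %*% matrix(rnorm(3 * sum(an$vent)), 3)
  vol <- vol_from_series(series, d)
  out <- tissue_regression(vol, an$wm, an$vent, an$gm)
  resgm <- t(matrix(out$data, V, nt))[, which(an$gm)]
  expect_lt(max(abs(resgm)) / sd(w), 0.05)

  # case 2: three ventricle signals mixed into gray matter -> <=1% variance left
  mix <- matrix(rnorm(3 * sum(an$gm)), 3)
  series2 <- series
  series2[, which(an$gm)] <- v3 %*% mix
  out2 <- tissue_regression(vol_from_series(series2, d), an$wm, an$vent, an$gm)
  res2 <- t(matrix(out2$data, V, nt))[, which(an$gm)]
  expect_lt(mean(colSums(res2^2)) / mean(colSums((v3 %*% mix)^2)), 0.01)

  # case 3: gray-matter signal orthogonal to all regressors passes through
  reg <- cbind(1, w, v3)
  qq <- qr.Q(qr(cbind(reg, rnorm(nt))))
  ortho <- qq[, ncol(qq)]  # orthogonal to regressors by construction
  series3 <- series
  series3[, which(an$gm)] <- ortho
  out3 <- tissue_regression(vol_from_series(series3, d), an$wm, an$vent, an$gm)
  res3 <- t(matrix(out3$data, V, nt))[, which(an$gm)[1]]
  expect_gt(cor(ortho, res3), 0.99)
})

test_that("preprocessing improves recovery of the generating correlation under nuisance mixing", {
  # paired comparison over simulated subjects with planted nuisance
  des <- quiet_design(n_subjects = 20, grid_shape = c(14, 14, 8), seed = 21,
                      noise_sd = 0.2, nuisance_mix = 0.5, motion_gain = 0,
                      te_slope_main = 0, te_slope_male = 0,
                      te_slope_female = 0)
  co <- simulate_cohort(des)
  sm_idx <- which(co$community == 1)
  err_raw <- err_pre <- numeric(length(co$images))
  for (s in seq_along(co$images)) {
    truth <- co$truth$coupling$rho_somatomotor[s]
    block_err <- function(vol) {
      Y <- t(matrix(vol$data, prod(dim(vol$data)[1:3]),
                    dim(vol$data)[4]))[retained_frames(vol), sm_idx]
      cm <- cor(Y)
      abs(mean(cm[upper.tri(cm)]) - truth)
    }
    err_raw[s] <- block_err(co$images[[s]])
    pp <- preprocess_subject(co$images[[s]], co$motion[[s]], co$masks,
                             fwhm_mm = 3)
    err_pre[s] <- block_err(pp$vol)
  }
  expect_lt(mean(err_pre), mean(err_raw))
})

test_that("single-subject preprocessing is deterministic and records its stage order", {
  des <- quiet_design(n_subjects = 2, grid_shape = c(10, 10, 6), seed = 13,
                      nuisance_mix = 0.3, motion_gain = 0.5)
  co <- simulate_cohort(des)
  p1 <- preprocess_subject(co$images[[1]], co$motion[[1]], co$masks)
  p2 <- preprocess_subject(co$images[[1]], co$motion[[1]], co$masks)
  expect_identical(p1$vol$data, p2$vol$data)
  expect_equal(p1$summary$order,
               c("truncate", "censor", "smooth", "motion_band_glm",
                 "tissue_regression"))
  # truncation contract: four frames dropped
  expect_equal(dim(p1$vol$data)[4], des$n_trs - 4L)
})
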