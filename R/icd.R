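#' Empirical survival curve of a voxel's positive correlations
#'
#' The intrinsic connectivity distribution summarises a voxel's whole-brain
#' connectivity through the distribution of its positive correlations with
#' all other gray-matter voxels. This constructor evaluates the empirical
#' survival function (fraction of positive correlations strictly exceeding
#' each threshold) on a fixed grid of correlation thresholds.
#'
#' @param r Numeric vector of correlation coefficients (the voxel's
#'   correlations with all other voxels); negative values are discarded.
#' @param tau Threshold grid in (0, 1).
#' @return Object of class `survival_curve`: `tau`, `survival`
#'   (non-increasing, in `[0, 1]`), `n_positive`.
#' @export
survival_curve <- function(r, tau = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(all(tau > 0), all(tau < 1), !is.unsorted(tau))
  pos <- sort(r[!is.na(r) & r > 0])
  np <- length(pos)
  surv <- if (np == 0L) rep(0, length(tau))
          else (np - findInterval(tau, pos)) / np
  structure(list(tau = tau, survival = surv, n_positive = np),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> %d positive correlations, S(0.25) = %.3f, S(0.5) = %.3f\n",
              x$n_positive,
              x$survival[which.min(abs(x$tau - 0.25))],
              x$survival[which.min(abs(x$tau - 0.5))]))
  invisible(x)
}

#' Survival curve of one voxel against all gray-matter voxels
#'
#' Pearson-correlates the voxel's time series (non-censored frames) with
#' every other gray-matter voxel and builds the positive-correlation
#' survival curve.
#'
#' @param vol Preprocessed [volume4d()].
#' @param gm_mask 3D logical gray-matter mask (at least two voxels).
#' @param voxel Voxel as a length-3 index vector or scalar linear index; must
#'   lie in the mask.
#' @param tau Threshold grid.
#' @return A [survival_curve()], or `NA` (with attribute `reason`) when the
#'   voxel has zero variance.
#' @export
voxel_correlations <- function(vol, gm_mask, voxel,
                               tau = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(inherits(vol, "volume4d"), sum(gm_mask) >= 2L)
  keep <- retained_frames(vol)
  if (length(keep) < 10L) stop("fewer than 10 non-censored frames")
  lin <- if (length(voxel) == 3L)
    coord_to_lin(matrix(as.integer(voxel), 1L), dim(gm_mask)) else as.integer(voxel)
  idx <- which(gm_mask)
  if (!(lin %in% idx)) stop("voxel not inside the gray-matter mask")
  Y <- mask_series(vol, gm_mask, keep)
  self <- match(lin, idx)
  y <- Y[, self]
  if (stats::sd(y) == 0) return(structure(NA, reason = "zero-variance voxel"))
  sds <- apply(Y, 2L, stats::sd)
  ok <- sds > 0
  ok[self] <- FALSE
  r <- suppressWarnings(as.vector(stats::cor(y, Y[, ok, drop = FALSE])))
  survival_curve(r, tau)
}

#' Stretched-exponential survival model
#'
#' `S(tau) = exp(-(alpha * tau)^beta)`. A smaller alpha gives uniformly
#' higher survival -- more strong connections -- matching the convention
#' that low alpha means high connectivity. This is the single point where
#' the decay model is defined; [fit_icd()] and [icd_grid_search()] both go
#' through it.
#'
#' @param tau Correlation thresholds in (0, 1).
#' @param alpha,beta Positive model parameters.
#' @return Model survival values.
#' @export
icd_model <- function(tau, alpha, beta) exp(-(alpha * tau)^beta)

# initial values from the log-log linearisation
#   log(-log S) = beta log(alpha) + beta log(tau)
.icd_init <- function(tau, S) {
  ok <- S > 1e-12 & S < 1 - 1e-12
  if (sum(ok) < 3L) return(c(1, 1))
  ll <- log(-log(S[ok])); lt <- log(tau[ok])
  b <- stats::cov(ll, lt) / stats::var(lt)
  if (!is.finite(b) || b <= 0) return(c(1, 1))
  a <- exp((mean(ll) - b * mean(lt)) / b)
  c(min(max(a, 1e-3), 1e3), min(max(b, 0.05), 20))
}

.icd_residfun <- function(tau, S) function(p) icd_model(tau, p[1], p[2]) - S

.icd_jacfun <- function(tau, S) function(p) {
  u <- (p[1] * tau)^p[2]
  e <- exp(-u)
  cbind(-e * u * p[2] / p[1], -e * u * log(p[1] * tau))
}

#' Fit the two-parameter intrinsic connectivity decay model
#'
#' Nonlinear least squares of the stretched-exponential survival model
#' `S(tau) = exp(-(alpha * tau)^beta)` against an empirical survival curve,
#' with both parameters constrained positive. A log-log linearisation
#' provides the starting point (falling back to `alpha = beta = 1`), and a
#' small lattice of restarts (`alpha` in \{0.5, 1, 2, 4\}, `beta` in
#' \{0.5, 1, 2\}) guards against non-convergence. Curves with fewer than
#' five strictly interior survival values (for example a curve identically
#' 1, which carries no decay information) are a fit failure, never a silent
#' zero.
#'
#' A smaller fitted `alpha` corresponds to uniformly higher survival --
#' more strong connections, i.e. higher connectivity; `beta` shapes the
#' decay.
#'
#' @param curve A [survival_curve()].
#' @param restarts Use the restart lattice when the primary fit fails.
#' @return Object of class `icd_fit`: `alpha`, `beta`, `rss`, `converged`,
#'   `curve`, `fitted`, `n_obs`. Failed fits have `converged = FALSE` and
#'   `NA` parameters.
#' @export
fit_icd <- function(curve, restarts = TRUE) {
  stopifnot(inherits(curve, "survival_curve"))
  tau <- curve$tau; S <- curve$survival
  fail <- function(reason) {
    structure(list(alpha = NA_real_, beta = NA_real_, rss = NA_real_,
                   converged = FALSE, reason = reason, curve = curve,
                   fitted = rep(NA_real_, length(tau)), n_obs = length(tau)),
              class = "icd_fit")
  }
  if (sum(S > 0 & S < 1) < 5L)
    return(fail("fewer than 5 interior survival values"))
  resfun <- .icd_residfun(tau, S)
  jacfun <- .icd_jacfun(tau, S)
  run <- function(start) {
    out <- tryCatch(
      minpack.lm::nls.lm(start, lower = c(1e-6, 1e-6), upper = c(1e4, 50),
                         fn = resfun, jac = jacfun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out)) return(NULL)
    list(par = out$par, rss = sum(out$fvec^2),
         ok = out$info %in% 1:4 && all(is.finite(out$par)))
  }
  best <- run(.icd_init(tau, S))
  if ((is.null(best) || !best$ok) && restarts) {
    for (a0 in c(0.5, 1, 2, 4)) for (b0 in c(0.5, 1, 2)) {
      cand <- run(c(a0, b0))
      if (!is.null(cand) && cand$ok &&
          (is.null(best) || !best$ok || cand$rss < best$rss)) best <- cand
    }
  }
  if (is.null(best) || !best$ok) return(fail("optimizer did not converge"))
  structure(list(alpha = best$par[[1]], beta = best$par[[2]], rss = best$rss,
                 converged = TRUE, reason = NULL, curve = curve,
                 fitted = icd_model(tau, best$par[[1]], best$par[[2]]),
                 n_obs = length(tau)),
            class = "icd_fit")
}

#' @export
print.icd_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<icd_fit> FAILED:", x$reason, "\n")
  } else {
    cat(sprintf("<icd_fit> alpha = %.4g, beta = %.4g, RSS = %.3g over %d thresholds\n",
                x$alpha, x$beta, x$rss, x$n_obs))
  }
  invisible(x)
}

#' @export
coef.icd_fit <- function(object, ...) c(alpha = object$alpha, beta = object$beta)

#' @export
predict.icd_fit <- function(object, newdata = NULL, ...) {
  tau <- if (is.null(newdata)) object$curve$tau
         else if (is.list(newdata)) newdata$tau else newdata
  icd_model(tau, object$alpha, object$beta)
}

#' @export
residuals.icd_fit <- function(object, ...) {
  object$curve$survival - object$fitted
}

#' @export
plot.icd_fit <- function(x, ...) {
  graphics::plot(x$curve$tau, x$curve$survival, pch = 16, cex = 0.5,
                 xlab = "correlation threshold", ylab = "survival",
                 main = "Intrinsic connectivity distribution fit", ...)
  if (x$converged)
    graphics::lines(x$curve$tau, x$fitted, col = 2, lwd = 2)
  invisible(x)
}

#' Grid-search reference optimum for the decay model
#'
#' Exhaustive evaluation of the least-squares objective on a dense (alpha,
#' beta) lattice. Intended as an independent check that [fit_icd()] reaches
#' the global optimum; never used by the fitting path.
#'
#' @param curve A [survival_curve()].
#' @param alpha_grid,beta_grid Lattice values.
#' @return List `alpha`, `beta`, `rss` of the best lattice point.
#' @export
icd_grid_search <- function(curve,
                            alpha_grid = exp(seq(log(0.05), log(20), length.out = 160)),
                            beta_grid = exp(seq(log(0.1), log(8), length.out = 120))) {
  g <- expand.grid(alpha = alpha_grid, beta = beta_grid)
  S <- curve$survival
  rss <- vapply(seq_len(nrow(g)), function(i)
    sum((icd_model(curve$tau, g$alpha[i], g$beta[i]) - S)^2), numeric(1))
  b <- which.min(rss)
  list(alpha = g$alpha[b], beta = g$beta[b], rss = rss[b])
}

#' Voxel-wise intrinsic connectivity distribution maps
#'
#' For every gray-matter voxel: Pearson correlations with all other
#' gray-matter voxels over the non-censored frames, positive-correlation
#' survival curve, and stretched-exponential fit. Correlations are computed
#' in voxel chunks so memory stays bounded; chunking does not change the
#' result. Per-voxel failures (zero variance, degenerate curves,
#' non-convergence) are propagated as `NA` with the reason counted, and the
#' computation aborts when more than `max_fail_frac` of voxels fail.
#'
#' @param vol Preprocessed [volume4d()].
#' @param gm_mask 3D logical gray-matter mask.
#' @param tau Threshold grid.
#' @param chunk_size Voxels correlated per chunk.
#' @param max_fail_frac Abort threshold on the voxel failure fraction.
#' @return Object of class `icd_maps`: 3D maps `alpha`, `beta`, `rss`,
#'   `n_positive`, logical `fail`, plus `gm_mask`, `affine`, `tau`,
#'   `n_fail`.
#' @export
icd_subject <- function(vol, gm_mask, tau = seq(0.01, 0.99, by = 0.01),
                        chunk_size = 512L, max_fail_frac = 0.2) {
  stopifnot(inherits(vol, "volume4d"), sum(gm_mask) >= 2L)
  keep <- retained_frames(vol)
  if (length(keep) < 10L) stop("fewer than 10 non-censored frames")
  Y <- mask_series(vol, gm_mask, keep)
  V <- ncol(Y)
  sds <- apply(Y, 2L, stats::sd)
  Z <- scale(Y)  # zero-variance voxels give NaN columns, handled below
  alpha <- beta <- rss <- numeric(V)
  npos <- integer(V)
  ok <- logical(V)
  ntau <- length(tau)
  for (lo in seq(1L, V, by = chunk_size)) {
    hi <- min(lo + chunk_size - 1L, V)
    cols <- lo:hi
    R <- crossprod(Z, Z[, cols, drop = FALSE]) / (length(keep) - 1L)
    for (jj in seq_along(cols)) {
      v <- cols[jj]
      if (sds[v] == 0) { alpha[v] <- NA; next }
      r <- R[, jj]
      r <- r[-v]
      r <- r[is.finite(r)]
      cv <- survival_curve(r, tau)
      npos[v] <- cv$n_positive
      ft <- fit_icd(cv)
      if (ft$converged) {
        alpha[v] <- ft$alpha; beta[v] <- ft$beta; rss[v] <- ft$rss
        ok[v] <- TRUE
      } else {
        alpha[v] <- NA
      }
    }
  }
  n_fail <- sum(!ok)
  if (n_fail / V > max_fail_frac)
    stop(sprintf("ICD failed for %d of %d voxels (> %.0f%%)", n_fail, V,
                 100 * max_fail_frac))
  to_map <- function(vals) {
    m <- array(NA_real_, dim(gm_mask))
    m[gm_mask] <- vals
    m
  }
  a <- to_map(alpha); b <- to_map(ifelse(ok, beta, NA))
  q <- to_map(ifelse(ok, rss, NA))
  np <- to_map(as.numeric(npos))
  fl <- array(FALSE, dim(gm_mask)); fl[gm_mask] <- !ok
  structure(list(alpha = a, beta = b, rss = q, n_positive = np, fail = fl,
                 gm_mask = gm_mask, affine = vol$affine, tau = tau,
                 n_fail = n_fail),
            class = "icd_maps")
}

#' @export
print.icd_maps <- function(x, ...) {
  cat(sprintf("<icd_maps> %d gray-matter voxels, %d failed; alpha median %.3g [%.3g, %.3g]\n",
              sum(x$gm_mask), x$n_fail,
              stats::median(x$alpha[x$gm_mask], na.rm = TRUE),
              stats::quantile(x$alpha[x$gm_mask], 0.05, na.rm = TRUE),
              stats::quantile(x$alpha[x$gm_mask], 0.95, na.rm = TRUE)))
  invisible(x)
}

#' Smooth fitted parameter maps
#'
#' Mask-renormalised Gaussian smoothing of the alpha and beta maps within
#' the gray-matter mask; voxels with failed fits are treated as missing and
#' excluded from the kernel normalisation.
#'
#' @param maps An [icd_subject()] result.
#' @param fwhm_mm Kernel FWHM in mm (default 4).
#' @return The `icd_maps` object with smoothed `alpha` and `beta`.
#' @export
smooth_parameter_map <- function(maps, fwhm_mm = 4) {
  stopifnot(inherits(maps, "icd_maps"))
  v <- voxel_size(maps$affine)
  maps$alpha <- smooth_map(maps$alpha, fwhm_mm, v, maps$gm_mask)
  maps$beta <- smooth_map(maps$beta, fwhm_mm, v, maps$gm_mask)
  maps
}
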