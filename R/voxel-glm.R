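#' Design matrix for the exposure-by-sex regression
#'
#' Six columns: intercept, capped exposure count (0-3), a male indicator
#' (female = 0, so the exposure coefficient is the female slope and the
#' interaction coefficient is the male-minus-female slope difference), the
#' sex-by-exposure product, age in years, and maternal education in years.
#'
#' @param subjects Data.frame with `te_coded`, `sex` (factor female/male),
#'   `age`, `maternal_education`.
#' @return Numeric matrix with one row per subject.
#' @export
build_design <- function(subjects) {
  stopifnot(all(c("te_coded", "sex", "age", "maternal_education") %in%
                  names(subjects)))
  if (anyNA(subjects[c("te_coded", "sex", "age", "maternal_education")]))
    stop("design covariates contain missing values; run apply_qc() first")
  if (!all(subjects$te_coded %in% 0:3)) stop("te_coded must be in 0..3")
  male <- as.numeric(subjects$sex == "male")
  X <- cbind(intercept = 1, te = subjects$te_coded, sex = male,
             sex_te = male * subjects$te_coded, age = subjects$age,
             maternal_education = subjects$maternal_education)
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (degenerate cohort: check that both sexes and several exposure levels are present)")
  X
}

#' Stack per-subject parameter maps for group analysis
#'
#' Collects one fitted parameter map per subject into a subjects-by-voxels
#' matrix over the voxels where every subject has a successful fit.
#'
#' @param maps_list List of [icd_subject()] results (one per subject).
#' @param what `"alpha"` or `"beta"`.
#' @return Object of class `param_stack`: `values` (n x V matrix), `mask`
#'   (3D logical analysis mask), `affine`, `dims`.
#' @export
stack_parameter_maps <- function(maps_list, what = c("alpha", "beta")) {
  what <- match.arg(what)
  stopifnot(length(maps_list) >= 2L)
  gm <- maps_list[[1]]$gm_mask
  ok <- gm
  for (m in maps_list) ok <- ok & !is.na(m[[what]])
  vals <- t(vapply(maps_list, function(m) m[[what]][ok], numeric(sum(ok))))
  structure(list(values = vals, mask = ok, affine = maps_list[[1]]$affine,
                 dims = dim(gm)),
            class = "param_stack")
}

#' Voxel-wise ordinary least squares
#'
#' Fits the full model at every voxel and returns estimates, standard
#' errors, t statistics and two-sided p values for all terms. Both alpha
#' and beta stacks are supported; residual degrees of freedom are
#' `n - n_terms`.
#'
#' @param stack A [stack_parameter_maps()] result, or a plain subjects x
#'   voxels matrix (then `mask`, `affine` must be given).
#' @param design Design matrix from [build_design()].
#' @param mask,affine Required when `stack` is a plain matrix.
#' @return Object of class `voxel_glm` with `coefficients`, `se`, `t`, `p`
#'   (terms x voxels matrices), `df`, `terms`, and the inputs needed for
#'   permutation inference (`X`, `Y`, `mask`, `dims`, `affine`).
#' @export
fit_voxelwise <- function(stack, design, mask = NULL, affine = NULL) {
  if (inherits(stack, "param_stack")) {
    Y <- stack$values; mask <- stack$mask; affine <- stack$affine
  } else {
    Y <- as.matrix(stack)
    stopifnot(!is.null(mask), !is.null(affine))
  }
  X <- design
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("stack and design disagree on the number of subjects")
  if (n < 10L) stop("need at least 10 subjects")
  XtXi <- tryCatch(solve(crossprod(X)), error = function(e)
    stop("design matrix is rank deficient: ", conditionMessage(e)))
  pinv <- XtXi %*% t(X)
  B <- pinv %*% Y
  res <- Y - X %*% B
  df <- n - p
  sigma2 <- colSums(res^2) / df
  se <- sqrt(outer(diag(XtXi), sigma2))
  tt <- B / se
  pv <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  structure(list(coefficients = B, se = se, t = tt, p = pv, df = df,
                 terms = colnames(X), X = X, Y = Y, XtXi = XtXi,
                 sigma2 = sigma2, mask = mask, dims = dim(mask),
                 affine = affine),
            class = "voxel_glm")
}

#' @export
print.voxel_glm <- function(x, ...) {
  cat(sprintf("<voxel_glm> %d subjects, %d voxels, %d terms (df = %d)\n",
              nrow(x$X), ncol(x$Y), length(x$terms), x$df))
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.voxel_glm <- function(object, ...) object$coefficients

#' @export
summary.voxel_glm <- function(object, ...) {
  sup <- colSums(t(object$p) < 0.001)
  out <- data.frame(term = object$terms,
                    median_coef = apply(object$coefficients, 1L, stats::median),
                    n_voxels_p_lt_0.001 = sup)
  rownames(out) <- NULL
  out
}

#' Sex-specific exposure slopes from the fitted model
#'
#' With female coded 0, the exposure coefficient is the female slope and the
#' male slope is the exposure coefficient plus the interaction coefficient.
#' Standard errors for the male slope combine the two sampling variances
#' and their covariance.
#'
#' @param fit A [fit_voxelwise()] result.
#' @return List of 3D maps: `female_slope`, `male_slope`, `female_se`,
#'   `male_se`.
#' @export
interaction_slopes <- function(fit) {
  stopifnot(inherits(fit, "voxel_glm"))
  it <- match("te", fit$terms); ix <- match("sex_te", fit$terms)
  if (anyNA(c(it, ix))) stop("fit lacks te and sex_te terms")
  female <- fit$coefficients[it, ]
  male <- female + fit$coefficients[ix, ]
  v <- fit$XtXi
  var_f <- v[it, it] * fit$sigma2
  var_m <- (v[it, it] + v[ix, ix] + 2 * v[it, ix]) * fit$sigma2
  to_map <- function(vals) {
    m <- array(NA_real_, fit$dims)
    m[fit$mask] <- vals
    m
  }
  list(female_slope = to_map(female), male_slope = to_map(male),
       female_se = to_map(sqrt(var_f)), male_se = to_map(sqrt(var_m)))
}

# t statistics for one term under Freedman-Lane surrogate data, vectorised
# over voxels. Precomputations are shared across permutations.
.fl_precompute <- function(X, term_idx) {
  Xr <- X[, -term_idx, drop = FALSE]
  qrr <- qr(Xr)
  Q <- qr.Q(qrr)
  xj <- X[, term_idx]
  xt <- xj - Q %*% crossprod(Q, xj)   # x_j residualised on the other columns
  list(Q = Q, xt = as.vector(xt), xx = sum(xt^2), Xr = Xr, qrr = qrr)
}

#' Cluster-extent correction by permutation
#'
#' Thresholds the voxel map of the named term at a two-sided p value,
#' groups supra-threshold voxels into connected components, and compares
#' each component against a max-cluster null distribution built by
#' Freedman-Lane permutation: residuals of the reduced model (the full
#' model without the tested term) are row-permuted, added back to the
#' reduced-model fit, the full model is refitted, and the maximum
#' supra-threshold cluster statistic is recorded. The cluster statistic is
#' the extent (voxel count) with ties between equal-sized clusters broken
#' by cluster mass (the summed excess of |t| over the threshold, squashed
#' into (0, 1) so that a larger extent always dominates); the mass
#' tie-break makes the statistic continuous, which avoids the
#' conservativeness a purely integer-valued extent suffers under
#' permutation testing when supra-threshold clusters are small. Clusters
#' with permutation-corrected p value
#' `(1 + #\{null >= stat\}) / (n_perm + 1)` at or below `cluster_alpha` are
#' retained; each is reported with its size, peak voxel (largest absolute
#' coefficient, ties broken by smallest linear index, coordinates in mm via
#' the affine), hemisphere of the peak (left of / right of the grid's x
#' midline), and average in-cluster coefficient.
#'
#' @param fit A [fit_voxelwise()] result.
#' @param term Term name (e.g. `"te"` or `"sex_te"`).
#' @param voxel_p Two-sided voxel-wise threshold (default 0.001).
#' @param cluster_alpha Cluster-level family-wise error target (default 0.05).
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed for the permutation draws.
#' @param connectivity Component adjacency: 6 (faces), 18 or 26.
#' @return Object of class `cluster_result`: data.frame `clusters` (possibly
#'   zero rows), list `masks` of cluster voxel masks, `null_max` (the
#'   permutation null), `size_threshold`, and metadata.
#' @export
cluster_correct <- function(fit, term, voxel_p = 0.001, cluster_alpha = 0.05,
                            n_perm = 1000L, seed = 1L, connectivity = 6L) {
  stopifnot(inherits(fit, "voxel_glm"))
  if (n_perm < 100L) stop("n_perm must be at least 100 for a usable null")
  j <- match(term, fit$terms)
  if (is.na(j)) stop("unknown term: ", term)
  X <- fit$X; Y <- fit$Y
  n <- nrow(X); df <- fit$df
  t_crit <- stats::qt(1 - voxel_p / 2, df)
  pre <- .fl_precompute(X, j)
  Br <- qr.coef(pre$qrr, Y)
  Er <- Y - pre$Xr %*% Br            # reduced-model residuals
  C <- colSums(Er^2)                 # invariant under row permutation
  mask_idx <- which(fit$mask)
  dims <- fit$dims

  # extent-with-mass-tie-break statistic for each component of a supra set
  comp_stats <- function(supra, tvals) {
    if (!any(supra)) return(list(lab = integer(0), stat = numeric(0)))
    lab <- label_components(mask_idx[supra], dims, connectivity)
    size <- tabulate(lab)
    mass <- as.vector(tapply(abs(tvals[supra]) - t_crit, lab, sum))
    list(lab = lab, stat = size + mass / (1 + mass))
  }
  max_stat <- function(supra, tvals) {
    cs <- comp_stats(supra, tvals)
    if (!length(cs$stat)) 0 else max(cs$stat)
  }
  t_from_resid <- function(E) {
    b <- as.vector(crossprod(pre$xt, E)) / pre$xx
    z <- crossprod(pre$Q, E)
    rss_r <- C - colSums(z^2)
    rss_f <- pmax(rss_r - b^2 * pre$xx, 0)
    b / sqrt(rss_f / df / pre$xx)
  }

  set.seed(seed)
  null_max <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    Ep <- Er[sample.int(n), , drop = FALSE]
    tstat <- t_from_resid(Ep)
    null_max[k] <- max_stat(abs(tstat) > t_crit, tstat)
  }
  stat_thr <- stats::quantile(null_max, 1 - cluster_alpha, type = 1,
                              names = FALSE)

  t_obs <- fit$t[j, ]
  supra_obs <- abs(t_obs) > t_crit
  clusters <- data.frame()
  masks <- list()
  if (any(supra_obs)) {
    cs <- comp_stats(supra_obs, t_obs)
    lin <- mask_idx[supra_obs]
    coefs <- fit$coefficients[j, supra_obs]
    for (cl in sort(unique(cs$lab))) {
      sel <- cs$lab == cl
      size <- sum(sel)
      cp <- (1 + sum(null_max >= cs$stat[cl])) / (n_perm + 1)
      if (cp > cluster_alpha) next
      cl_lin <- lin[sel]
      cl_coef <- coefs[sel]
      pk <- cl_lin[order(-abs(cl_coef), cl_lin)][1L]
      pk_mm <- vox_to_mm(lin_to_coord(pk, dims), fit$affine)
      midline <- vox_to_mm(c((dims[1] + 1) / 2, 1, 1), fit$affine)[1]
      cm <- array(FALSE, dims); cm[cl_lin] <- TRUE
      masks[[length(masks) + 1L]] <- cm
      clusters <- rbind(clusters, data.frame(
        cluster = length(masks), size = size,
        hemisphere = if (pk_mm[1] < midline) "Left" else "Right",
        peak_x = pk_mm[1], peak_y = pk_mm[2], peak_z = pk_mm[3],
        average_effect = mean(cl_coef),
        corrected_p = cp))
    }
    if (nrow(clusters)) {
      ord <- order(-clusters$size)
      clusters <- clusters[ord, , drop = FALSE]
      masks <- masks[ord]
      clusters$cluster <- seq_len(nrow(clusters))
      rownames(clusters) <- NULL
    }
  }
  structure(list(clusters = clusters, masks = masks, null_max = null_max,
                 stat_threshold = stat_thr,
                 meta = list(term = term, voxel_p = voxel_p,
                             cluster_alpha = cluster_alpha, n_perm = n_perm,
                             seed = seed, connectivity = connectivity,
                             method = "Freedman-Lane max-cluster permutation (extent with mass tie-break)")),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> term %s: %d significant cluster(s); null cluster-statistic threshold %.2f (%d permutations)\n",
              x$meta$term, nrow(x$clusters), x$stat_threshold, x$meta$n_perm))
  if (nrow(x$clusters)) print(x$clusters, digits = 4)
  invisible(x)
}
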