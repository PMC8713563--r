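#' Seed-based connectivity map for one subject
#'
#' Averages the preprocessed time series over the seed voxels (non-censored
#' frames), Pearson-correlates it with every gray-matter voxel, and applies
#' the Fisher variance-stabilising transform `z = atanh(r)` with `|r|`
#' clipped at `1 - 1e-7` so self-correlations stay finite.
#'
#' @param vol Preprocessed [volume4d()].
#' @param seed_mask 3D logical array of seed voxels (nonempty).
#' @param gm_mask 3D logical gray-matter mask.
#' @return 3D map of Fisher z values (`NA` outside the gray-matter mask).
#' @export
seed_connectivity <- function(vol, seed_mask, gm_mask) {
  stopifnot(inherits(vol, "volume4d"), any(seed_mask))
  keep <- retained_frames(vol)
  seed_ts <- rowMeans(mask_series(vol, seed_mask, keep))
  if (stats::sd(seed_ts) == 0)
    stop("seed time series is constant: subject flagged")
  Y <- mask_series(vol, gm_mask, keep)
  sds <- apply(Y, 2L, stats::sd)
  r <- rep(0, ncol(Y))
  r[sds > 0] <- as.vector(stats::cor(seed_ts, Y[, sds > 0, drop = FALSE]))
  r <- pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  out <- array(NA_real_, dim(gm_mask))
  out[gm_mask] <- z
  out
}

#' Group-level network from subject z maps
#'
#' One-sample two-sided t test per voxel on the Fisher z values across
#' subjects, Benjamini-Hochberg q values over the gray-matter voxels, and a
#' network mask of voxels passing both the p and the FDR threshold (and,
#' by default, carrying a positive mean z). The default thresholds here are
#' intentionally configurable: the very stringent published-scale values
#' (p < 1e-44, FDR < 3e-16) presuppose a sample of many hundreds of
#' subjects, and desk-scale cohorts require looser settings such as
#' p < 1e-6, FDR < 1e-4.
#'
#' @param z_maps List of 3D z maps, or a subjects x voxels matrix.
#' @param gm_mask 3D logical gray-matter mask (required when `z_maps` is a
#'   matrix; otherwise taken from the map geometry).
#' @param p_thresh Voxel-wise p threshold.
#' @param fdr_thresh Voxel-wise Benjamini-Hochberg q threshold.
#' @param positive_only Restrict the network to voxels with positive mean z.
#' @return Object of class `network_map`: 3D `mean_z`, `t`, `p`, `q`,
#'   logical `network_mask`, `n_voxels`, `n_subjects`.
#' @export
group_network <- function(z_maps, gm_mask = NULL, p_thresh = 1e-6,
                          fdr_thresh = 1e-4, positive_only = TRUE) {
  if (is.list(z_maps)) {
    stopifnot(length(z_maps) >= 2L)
    if (is.null(gm_mask)) gm_mask <- !is.na(z_maps[[1]])
    Z <- t(vapply(z_maps, function(m) m[gm_mask], numeric(sum(gm_mask))))
  } else {
    Z <- as.matrix(z_maps)
    stopifnot(!is.null(gm_mask), nrow(Z) >= 2L)
  }
  n <- nrow(Z)
  mu <- colMeans(Z)
  sdv <- apply(Z, 2L, stats::sd)
  tt <- rep(0, ncol(Z))
  pv <- rep(1, ncol(Z))
  ok <- sdv > 0
  if (any(!ok))
    message(sprintf("%d voxel(s) with zero variance across subjects: p set to 1",
                    sum(!ok)))
  tt[ok] <- mu[ok] / (sdv[ok] / sqrt(n))
  pv[ok] <- 2 * stats::pt(abs(tt[ok]), n - 1, lower.tail = FALSE)
  qv <- stats::p.adjust(pv, method = "BH")
  sel <- pv < p_thresh & qv < fdr_thresh
  if (positive_only) sel <- sel & mu > 0
  to_map <- function(vals, fill = NA_real_) {
    m <- array(fill, dim(gm_mask))
    m[gm_mask] <- vals
    m
  }
  mask_net <- array(FALSE, dim(gm_mask))
  mask_net[gm_mask] <- sel
  structure(list(mean_z = to_map(mu), t = to_map(tt), p = to_map(pv),
                 q = to_map(qv), network_mask = mask_net,
                 n_voxels = sum(sel), n_subjects = n,
                 thresholds = c(p = p_thresh, fdr = fdr_thresh)),
            class = "network_map")
}

#' @export
print.network_map <- function(x, ...) {
  cat(sprintf("<network_map> %d voxels pass p < %.3g & FDR < %.3g (n = %d subjects)\n",
              x$n_voxels, x$thresholds[["p"]], x$thresholds[["fdr"]],
              x$n_subjects))
  invisible(x)
}

#' Overlap of a network with a 7-label reference parcellation
#'
#' For each reference label 1-7, the percentage of network voxels carrying
#' that label, plus the percentage unlabeled; the percentages sum to 100.
#'
#' @param net A [group_network()] result or a 3D logical mask.
#' @param parc 3D integer parcellation (labels 0-7; 0 = unlabeled) on the
#'   same grid.
#' @return Data.frame with columns `label` (0-7, 0 meaning unlabeled),
#'   `n_voxels`, `percent`.
#' @export
overlap_with_reference <- function(net, parc) {
  mask <- if (inherits(net, "network_map")) net$network_mask else net
  if (!all(dim(mask) == dim(parc))) stop("network and parcellation grids differ")
  labs <- parc[mask]
  n <- length(labs)
  counts <- vapply(0:7, function(l) sum(labs == l), integer(1))
  data.frame(label = 0:7, n_voxels = counts,
             percent = if (n > 0) 100 * counts / n else rep(0, 8))
}

#' Directional overlap between two constructed networks
#'
#' Percentage of the voxels of network `b` that lie inside network `a`
#' (`|A intersect B| / |B| * 100`), the convention used when reporting how
#' much of a smaller network is contained in a larger one.
#'
#' @param a,b [group_network()] results or 3D logical masks.
#' @return A single percentage.
#' @export
pairwise_overlap <- function(a, b) {
  ma <- if (inherits(a, "network_map")) a$network_mask else a
  mb <- if (inherits(b, "network_map")) b$network_mask else b
  if (!all(dim(ma) == dim(mb))) stop("network grids differ")
  nb <- sum(mb)
  if (nb == 0L) return(NA_real_)
  100 * sum(ma & mb) / nb
}
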