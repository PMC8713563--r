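#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated list.
#' Unknown keys (at either level) are rejected before any computation, and
#' the fully resolved configuration is written alongside every run's
#' outputs.
#'
#' @param seed Master seed; every random draw in a run flows from it.
#' @param sim Named list of overrides passed to [sim_design()].
#' @param qc List: `motion_mm`, `censor_max` (see [apply_qc()]).
#' @param preprocess List: `n_drop`, `fwhm_mm`, `movement_mm`,
#'   `outlier_frac`, `band_hz`.
#' @param icd List: `tau_step` (threshold grid spacing), `fwhm_mm`
#'   (parameter-map smoothing), `chunk_size`.
#' @param glm List: `parameter` ("alpha" or "beta"), `terms` (tested
#'   contrasts), `voxel_p`, `cluster_alpha`, `n_perm`, `connectivity`.
#' @param network List: `p_thresh`, `fdr_thresh`, `positive_only`,
#'   `max_seeds` (seed clusters analysed per term). The published-scale
#'   thresholds (p < 1e-44, FDR < 3e-16) presume a cohort of many hundreds;
#'   the defaults here suit desk-scale simulated cohorts.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = list(),
                            qc = list(motion_mm = 0.3, censor_max = 0.3),
                            preprocess = list(n_drop = 4L, fwhm_mm = 6,
                                              movement_mm = 0.3,
                                              outlier_frac = 0.10,
                                              band_hz = c(0.01, 0.08)),
                            icd = list(tau_step = 0.01, fwhm_mm = 4,
                                       chunk_size = 512L),
                            glm = list(parameter = "alpha",
                                       terms = c("te", "sex_te"),
                                       voxel_p = 0.001, cluster_alpha = 0.05,
                                       n_perm = 500L, connectivity = 6L),
                            network = list(p_thresh = 1e-6, fdr_thresh = 1e-4,
                                           positive_only = TRUE,
                                           max_seeds = 3L)) {
  defaults <- formals(pipeline_config)
  cfg <- list(seed = as.integer(seed), sim = sim, qc = qc,
              preprocess = preprocess, icd = icd, glm = glm,
              network = network)
  for (section in c("qc", "preprocess", "icd", "glm", "network")) {
    def <- eval(defaults[[section]])
    unknown <- setdiff(names(cfg[[section]]), names(def))
    if (length(unknown))
      stop(sprintf("unknown key(s) in config section '%s': %s", section,
                   paste(unknown, collapse = ", ")))
    cfg[[section]] <- utils::modifyList(def, cfg[[section]])
  }
  unknown_sim <- setdiff(names(cfg$sim), names(formals(sim_design)))
  if (length(unknown_sim))
    stop("unknown key(s) in config section 'sim': ",
         paste(unknown_sim, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> seed %d, GLM on %s (%s), %d permutations\n",
              x$seed, x$glm$parameter, paste(x$glm$terms, collapse = " + "),
              x$glm$n_perm))
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

# deterministic TSV writer (fixed significant digits, no quoting)
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate -> score/QC -> preprocess -> ICD -> parameter-map
#' smoothing -> voxel-wise GLM with cluster correction -> seed-based
#' networks -> parcellation overlap, writing the statistical tables and a
#' manifest of the fully resolved configuration to `out_dir`. Two runs with
#' the same configuration produce byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param cohort Optionally a pre-built `synthetic_cohort` to analyse
#'   (otherwise one is simulated from `config$sim` with `config$seed`).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with every intermediate object: `cohort`,
#'   `qc`, `demographics`, `icd_maps`, `glm_fit`, `clusters` (per term),
#'   `networks`, `overlaps`, `pairwise`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         cohort = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(cohort)) {
    sim_args <- config$sim
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    design <- do.call(sim_design, sim_args)
    say("simulate: %d subjects on a %s grid", design$n_subjects,
        paste(design$grid_shape, collapse = "x"))
    cohort <- simulate_cohort(design)
  }
  n <- length(cohort$images)
  pp <- config$preprocess

  # stage 1: truncation + censoring gives the motion summaries QC needs
  say("preprocess: truncation and frame censoring")
  stage1 <- vector("list", n)
  for (s in seq_len(n)) {
    tr0 <- drop_initial_frames(cohort$images[[s]], cohort$motion[[s]], pp$n_drop)
    vol <- censor_frames(tr0$vol, tr0$motion, pp$movement_mm, pp$outlier_frac)
    stage1[[s]] <- list(vol = vol, motion = tr0$motion)
  }
  subjects <- cohort$subjects
  subjects$mean_motion_per_tr <-
    vapply(stage1, function(x) mean_motion(x$motion), numeric(1))
  subjects$censor_fraction <-
    vapply(stage1, function(x) attr(x$vol, "censor_fraction"), numeric(1))

  qc <- apply_qc(subjects, config$qc$motion_mm, config$qc$censor_max)
  say("qc: %d of %d subjects included", nrow(qc$included), n)
  if (nrow(qc$included) < 10L) stop("fewer than 10 subjects pass QC")
  demo <- demographics_table(qc$included)

  # stage 2: smoothing, nuisance GLM, tissue regression for included subjects
  inc_idx <- match(qc$included$subject_id, subjects$subject_id)
  brain <- cohort$masks$gm | cohort$masks$wm | cohort$masks$vent
  say("preprocess: smoothing + nuisance regression for %d subjects",
      length(inc_idx))
  pre <- list()
  pre_fail <- character(0)
  for (s in inc_idx) {
    res <- tryCatch({
      vol <- smooth_gaussian(stage1[[s]]$vol, pp$fwhm_mm, cohort$masks$gm)
      vol <- nuisance_glm(vol, stage1[[s]]$motion, pp$band_hz, brain)
      tissue_regression(vol, cohort$masks$wm, cohort$masks$vent,
                        cohort$masks$gm)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      pre_fail <- c(pre_fail, subjects$subject_id[s])
    } else pre[[subjects$subject_id[s]]] <- res
  }
  if (length(pre_fail)) {
    say("preprocess: %d subject(s) dropped (%s)", length(pre_fail),
        paste(pre_fail, collapse = ", "))
    drop <- qc$included$subject_id %in% pre_fail
    moved <- qc$included[drop, , drop = FALSE]
    moved$qc_pass <- FALSE
    moved$exclusion_reason <- "preprocess_failure"
    qc$excluded <- rbind(qc$excluded, moved)
    qc$included <- qc$included[!drop, , drop = FALSE]
  }
  included <- qc$included

  say("icd: fitting parameter maps for %d subjects", nrow(included))
  tau <- seq(config$icd$tau_step, 1 - config$icd$tau_step,
             by = config$icd$tau_step)
  maps <- lapply(included$subject_id, function(id) {
    m <- icd_subject(pre[[id]], cohort$masks$gm, tau, config$icd$chunk_size)
    smooth_parameter_map(m, config$icd$fwhm_mm)
  })

  stack <- stack_parameter_maps(maps, config$glm$parameter)
  X <- build_design(included)
  fit <- fit_voxelwise(stack, X)
  clusters <- list()
  for (ti in seq_along(config$glm$terms)) {
    term <- config$glm$terms[[ti]]
    say("glm: cluster correction for term '%s'", term)
    clusters[[term]] <- cluster_correct(
      fit, term, config$glm$voxel_p, config$glm$cluster_alpha,
      config$glm$n_perm, seed = config$seed + 1000L + ti,
      connectivity = config$glm$connectivity)
  }

  # seed-based networks from the significant clusters, in cluster order
  say("network: seed-based maps and parcellation overlap")
  seeds <- list()
  for (term in names(clusters)) {
    cres <- clusters[[term]]
    k <- min(nrow(cres$clusters), config$network$max_seeds)
    for (i in seq_len(k))
      seeds[[sprintf("%s_cluster%d", term, i)]] <- cres$masks[[i]]
  }
  networks <- list(); overlaps <- list(); pairwise <- data.frame()
  for (nm in names(seeds)) {
    zmaps <- lapply(included$subject_id, function(id)
      seed_connectivity(pre[[id]], seeds[[nm]], cohort$masks$gm))
    net <- group_network(zmaps, cohort$masks$gm, config$network$p_thresh,
                         config$network$fdr_thresh,
                         config$network$positive_only)
    networks[[nm]] <- net
    ov <- overlap_with_reference(net, cohort$parcellation)
    ov <- cbind(network = nm, ov)
    overlaps[[nm]] <- ov
  }
  if (length(networks) > 1L) {
    first <- networks[[1L]]
    for (nm in names(networks)[-1L]) {
      pairwise <- rbind(pairwise, data.frame(
        network = nm, reference = names(networks)[1L],
        percent_inside = pairwise_overlap(first, networks[[nm]])))
    }
  }

  if (!is.null(out_dir)) {
    qc_report <- rbind(qc$included, qc$excluded)
    qc_report <- qc_report[order(qc_report$subject_id),
                           c("subject_id", "te_count_raw", "te_coded",
                             "mean_motion_per_tr", "censor_fraction",
                             "qc_pass", "exclusion_reason")]
    write_tsv(qc_report, file.path(out_dir, "qc_report.tsv"))
    write_tsv(demo, file.path(out_dir, "demographics.tsv"))
    for (term in names(clusters))
      write_tsv(clusters[[term]]$clusters,
                file.path(out_dir, sprintf("clusters_%s.tsv", term)))
    if (length(overlaps))
      write_tsv(do.call(rbind, overlaps), file.path(out_dir, "overlap.tsv"))
    if (nrow(pairwise))
      write_tsv(pairwise, file.path(out_dir, "pairwise_overlap.tsv"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      manifest <- list(
        package_version = as.character(utils::packageVersion("rsicd")),
        config = unclass(config),
        n_subjects = n, n_included = nrow(included),
        exclusions = as.list(qc$counts),
        coupling_clipped = cohort$truth$n_clipped,
        n_networks = length(networks))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }

  invisible(list(cohort = cohort, qc = qc, demographics = demo,
                 icd_maps = maps, stack = stack, glm_fit = fit,
                 clusters = clusters, networks = networks,
                 overlaps = overlaps, pairwise = pairwise,
                 preprocessed = pre, config = config))
}
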