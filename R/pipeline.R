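# End-to-end orchestration: one config drives design generation, BOLD
# simulation, GLM/PSC, cross-validated recoding, the ROI ANOVA, the
# single-voxel selectivity analysis and the leave-one-run-out decoder, and
# writes the report bundle as delimited text files.

#' Default pipeline configuration
#'
#' Defaults reproduce the study parameters: 21 subjects, 9 runs, 3
#' selection runs (84 splits), 10,000 shuffles, 100 bins, and the eight
#' ROIs with their voxel counts. Tuning mixtures and effect sizes are free
#' simulation parameters (see the methods vignette).
#'
#' @param seed Master seed.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed = 1L) {
  rois <- lapply(names(ROI_VOXEL_COUNTS), function(r)
    list(n_voxels = ROI_VOXEL_COUNTS[[r]],
         mixture = c(0.25, 0.25, 0.25, 0.25)))
  names(rois) <- names(ROI_VOXEL_COUNTS)
  # NPC3 is modelled action-numerosity dominant; MTG ball dominant --
  # the tuning structure the analyses are designed to detect
  rois[["NPC3_L"]]$mixture <- c(0.6, 0.1, 0.15, 0.15)
  rois[["MTG_L"]]$mixture <- c(0.1, 0.6, 0.15, 0.15)
  list(
    seed = as.integer(seed),
    n_subjects = 21L, n_runs = 9L, k_selection = 3L,
    n_shuffles = 10000L, n_bins = 100L,
    rois = rois, reference_roi = "NPC3_L",
    baseline = 100, attend_gain = 0.3, delta = 0.5, noise_sd = 1,
    param_jitter = 0.2, subject_gain_sd = 0.2, subject_baseline_sd = 2,
    lag_tr = 2L, svm_cost = 1, svm_scale = FALSE,
    run_anova = TRUE, run_selectivity = TRUE, run_mvpa = TRUE,
    refined_group = TRUE
  )
}

#' Validate a pipeline configuration
#'
#' @param config Configuration list.
#' @return Character vector of problems (empty if valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(is.numeric(config$seed) && length(config$seed) == 1L, "seed must be a single integer")
  need(config$n_subjects >= 2, "n_subjects must be at least 2")
  need(config$n_runs == 9L, "the design generator requires n_runs = 9")
  need(config$k_selection >= 1 && config$k_selection < config$n_runs,
       "k_selection must be in 1..n_runs-1")
  need(config$n_shuffles >= 1, "n_shuffles must be positive")
  need(config$n_bins >= 2, "n_bins must be at least 2")
  need(config$noise_sd >= 0, "noise_sd must be non-negative")
  need(config$baseline > 0, "baseline must be positive")
  need(length(config$rois) >= 1, "at least one ROI is required")
  for (r in names(config$rois)) {
    mix <- config$rois[[r]]$mixture
    if (length(mix) != 4L || any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
      problems <- c(problems, paste0("ROI ", r, ": invalid class mixture"))
    if (config$rois[[r]]$n_voxels < 1)
      problems <- c(problems, paste0("ROI ", r, ": n_voxels must be positive"))
  }
  if (!is.null(config$reference_roi) && length(config$rois) &&
      !config$reference_roi %in% names(config$rois))
    problems <- c(problems, "reference_roi is not among the configured ROIs")
  problems
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) base[[nm]] <- cfg[[nm]]
  base
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes design -> simulate -> GLM/PSC -> recode -> ANOVA ->
#' selectivity -> decoding under one config and, if `out_dir` is given,
#' writes the report bundle: events TSVs, ANOVA table, group-average
#' selectivity table (below-diagonal % with paired t and chi-square against
#' the reference ROI), shuffled-null table (mean, SD, SD-distance),
#' per-subject group proportion table, decoding table, per-ROI scatter
#' exports, and a run log with the seed.
#'
#' @param config Configuration list (see [default_config()]).
#' @param out_dir Output directory, or NULL to skip writing.
#' @return List with the per-stage results (`session`, `recoded`,
#'   `anova`, `selectivity`, `null`, `group`, `mvpa`, tables).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid config:\n", paste("-", problems, collapse = "\n"))
  t0 <- Sys.time()
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("n_subjects: %d", config$n_subjects))
  stage <- function(name) log_lines <<- c(log_lines,
    sprintf("%s: %.1fs", name, as.numeric(Sys.time() - t0, units = "secs")))

  # --- design -------------------------------------------------------------
  videos <- enumerate_videos()
  v72 <- select_balanced_subset(videos, seed = config$seed)
  session <- build_session(v72, seed = config$seed + 1L)
  stage("design")

  # --- simulate + GLM + recode, per ROI -----------------------------------
  rois <- names(config$rois)
  recoded <- list(); populations <- list()
  for (i in seq_along(rois)) {
    roi <- rois[i]
    pop <- make_population(
      roi, mixture = config$rois[[roi]]$mixture,
      n_voxels = config$rois[[roi]]$n_voxels,
      baseline = config$baseline, attend_gain = config$attend_gain,
      delta = config$delta, noise_sd = config$noise_sd,
      param_jitter = config$param_jitter, seed = config$seed + 10L + i)
    populations[[roi]] <- pop
    recoded[[roi]] <- lapply(seq_len(config$n_subjects), function(s) {
      subj <- simulate_subject(
        pop, session, subject_id = s, seed = config$seed + 100L * i,
        subject_gain_sd = config$subject_gain_sd,
        subject_baseline_sd = config$subject_baseline_sd)
      psc <- subject_psc(subj)
      rec <- recode_all(psc, k = config$k_selection,
                        tie_seed = config$seed + s,
                        keep_replications = config$refined_group)
      rec$subject <- subj        # kept for the decoder
      rec
    })
  }
  stage("simulate_glm_recode")

  out <- list(config = config, session = session,
              populations = populations, recoded = recoded)

  # --- ROI ANOVA ----------------------------------------------------------
  if (isTRUE(config$run_anova)) {
    roi_means <- lapply(recoded, function(rs)
      roi_average(lapply(rs, `[[`, "mean")))
    out$anova <- anova_table(roi_means)
    stage("anova")
  }

  # --- selectivity --------------------------------------------------------
  if (isTRUE(config$run_selectivity)) {
    ref <- config$reference_roi
    sel_rows <- list(); null_rows <- list(); group_rows <- list()
    scatters <- list(); nulls <- list()
    ref_points <- compute_scatter(lapply(recoded[[ref]], `[[`, "mean"))
    ref_prop <- prop_below_diagonal(ref_points)
    ref_group <- group_prop_analysis(recoded[[ref]],
                                     refined = isTRUE(config$refined_group))
    for (roi in rois) {
      recs <- lapply(recoded[[roi]], `[[`, "mean")
      pts <- compute_scatter(recs)
      scatters[[roi]] <- pts
      prop <- prop_below_diagonal(pts)
      tt <- paired_t_voxels(pts)
      chi <- if (roi == ref) list(chi2 = NA_real_, p = NA_real_)
             else pairwise_chi2(ref_prop, config$rois[[ref]]$n_voxels,
                                prop, config$rois[[roi]]$n_voxels)
      sel_rows[[roi]] <- data.frame(
        roi = roi, n_voxels = config$rois[[roi]]$n_voxels,
        pct_below = prop, t = tt$t, df = tt$df, p = tt$p,
        chi2_vs_ref = chi$chi2, chi2_p = chi$p)
      nl <- shuffle_null(recs, n_shuffles = config$n_shuffles,
                         n_bins = config$n_bins,
                         seed = config$seed + 7L + match(roi, rois))
      nulls[[roi]] <- nl
      null_rows[[roi]] <- data.frame(
        roi = roi, null_mean = nl$mean, null_sd = nl$sd,
        sd_distance = sd_distance(prop, nl))
      grp <- group_prop_analysis(recoded[[roi]],
                                 refined = isTRUE(config$refined_group))
      pt <- if (roi == ref) list(t = NA_real_, df = NA_real_, p = NA_real_)
            else paired_t_rois(ref_group$subject_props, grp$subject_props)
      group_rows[[roi]] <- data.frame(
        roi = roi, mean = grp$mean, sd = grp$sd, t = grp$t, df = grp$df,
        p = grp$p, paired_t_vs_ref = pt$t, paired_p = pt$p)
    }
    out$selectivity <- do.call(rbind, sel_rows)
    out$null <- do.call(rbind, null_rows)
    out$group <- do.call(rbind, group_rows)
    out$scatters <- scatters
    out$nulls <- nulls
    rownames(out$selectivity) <- rownames(out$null) <-
      rownames(out$group) <- NULL
    stage("selectivity")
  }

  # --- decoding -----------------------------------------------------------
  if (isTRUE(config$run_mvpa)) {
    mvpa_rows <- lapply(rois, function(roi) {
      samples <- lapply(recoded[[roi]], function(rec) {
        subj <- rec$subject
        lapply(subj$runs, function(rn)
          extract_trial_samples(rn$bold, rn$schedule,
                                lag_tr = config$lag_tr))
      })
      res <- decode_roi(samples, cost = config$svm_cost,
                        scale = isTRUE(config$svm_scale))
      data.frame(roi = roi, mean_accuracy = res$mean, sd = res$sd,
                 chance = res$chance)
    })
    out$mvpa <- do.call(rbind, mvpa_rows)
    rownames(out$mvpa) <- NULL
    stage("mvpa")
  }

  # --- report bundle ------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    for (sched in session)
      export_events(sched, file.path(out_dir,
        sprintf("events_run-%02d.tsv", sched$run_index)))
    if (!is.null(out$anova)) wt(out$anova, "roi_anova.tsv")
    if (!is.null(out$selectivity)) {
      wt(out$selectivity, "selectivity_group_average.tsv")
      wt(out$null, "shuffle_null.tsv")
      wt(out$group, "selectivity_group.tsv")
      for (roi in names(out$scatters))
        wt(out$scatters[[roi]], sprintf("scatter_%s.tsv", roi))
    }
    if (!is.null(out$mvpa)) wt(out$mvpa, "mvpa_decoding.tsv")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  out$log <- log_lines
  out
}
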