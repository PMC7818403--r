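# Per-run GLM fitting and conversion of betas to percent signal change
# relative to the active-fixation condition, plus per-trial MR sample
# extraction for decoding.

#' Build a run design matrix
#'
#' Condition regressors are video-period boxcars grouped by block label and
#' convolved with the canonical HRF; the `three_condition` variant groups
#' "1-action"/"3-actions" into Action and "1-ball"/"3-balls" into Ball. The
#' fixation regressor models the 5.4-s fixation periods. Six motion series
#' and an explicit baseline (intercept) column are appended, giving 9
#' regressors plus baseline for `three_condition` and 11 plus baseline for
#' `five_condition`.
#'
#' @param schedule Run schedule.
#' @param motion Matrix n_TR x 6 of motion regressors.
#' @param variant `"five_condition"` (default) or `"three_condition"`.
#' @return Matrix n_TR x p with labelled columns; attribute
#'   `model_variant`.
#' @export
build_design_matrix <- function(schedule, motion,
                                variant = c("five_condition",
                                            "three_condition")) {
  variant <- match.arg(variant)
  n_tr <- schedule_n_tr(schedule)
  if (nrow(motion) != n_tr) stop("motion length does not match schedule")
  cond <- condition_regressors(schedule)
  if (variant == "three_condition") {
    cond <- cbind(Action = cond[, "1-action"] + cond[, "3-actions"],
                  Ball = cond[, "1-ball"] + cond[, "3-balls"],
                  Fix = cond[, "fixation"])
  } else {
    colnames(cond)[colnames(cond) == "fixation"] <- "Fix"
  }
  X <- cbind(cond, motion, baseline = 1)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  attr(X, "model_variant") <- variant
  X
}

#' Fit an ordinary-least-squares GLM for a matrix of voxels
#'
#' @param bold Matrix voxels x TRs (a single voxel may be a vector).
#' @param X Design matrix from [build_design_matrix()].
#' @return Matrix voxels x regressors of beta estimates, with the design's
#'   column names.
#' @export
fit_glm <- function(bold, X) {
  if (is.vector(bold)) bold <- matrix(bold, nrow = 1L)
  if (ncol(bold) != nrow(X)) stop("bold and design dimensions disagree")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  betas <- t(qr.coef(qx, t(bold)))
  colnames(betas) <- colnames(X)
  betas
}

#' Convert betas to percent signal change relative to active fixation
#'
#' For each experimental condition c, PSC_c = 100 (beta_c - beta_Fix) /
#' beta_baseline. The fixation condition is the reference and is not
#' returned (its PSC is identically zero).
#'
#' @param betas Matrix from [fit_glm()].
#' @return Matrix voxels x conditions of PSC values in percent.
#' @export
percent_signal_change <- function(betas) {
  if (is.vector(betas)) betas <- matrix(betas, nrow = 1L,
                                        dimnames = list(NULL, names(betas)))
  base <- betas[, "baseline"]
  if (any(base <= 0)) stop("non-positive baseline beta")
  conds <- setdiff(colnames(betas),
                   c("Fix", "baseline", paste0("motion", 1:6)))
  psc <- 100 * (betas[, conds, drop = FALSE] - betas[, "Fix"]) / base
  colnames(psc) <- conds
  psc
}

#' Per-run, per-condition PSC for one subject
#'
#' Fits the five-condition GLM run by run and returns the PSC tensor used
#' by the cross-validated recoding.
#'
#' @param subject Subject dataset from [simulate_subject()] (or any list of
#'   runs with `bold`, `motion`, `schedule`).
#' @return Array voxels x runs x 4 sub-conditions, dimnames on the
#'   condition axis.
#' @export
subject_psc <- function(subject) {
  runs <- subject$runs
  psc_list <- lapply(runs, function(rn) {
    X <- build_design_matrix(rn$schedule, rn$motion, "five_condition")
    percent_signal_change(fit_glm(rn$bold, X))[, BLOCK_LABELS, drop = FALSE]
  })
  n_vox <- nrow(psc_list[[1L]])
  out <- array(NA_real_, c(n_vox, length(runs), 4L),
               dimnames = list(NULL, NULL, BLOCK_LABELS))
  for (r in seq_along(runs)) out[, r, ] <- psc_list[[r]]
  out
}

#' Extract per-trial MR samples for decoding
#'
#' For each discrimination trial, takes the two TRs spanning the video
#' period, shifted by a hemodynamic lag (default 2 TRs = 5.4 s), and
#' expresses them as percent change relative to the mean of the run's
#' (equally lag-shifted) fixation-period TRs.
#'
#' @param bold Matrix voxels x TRs for one run.
#' @param schedule The run's schedule.
#' @param lag_tr Hemodynamic lag in TRs.
#' @param labels Block labels to extract (default the two action
#'   sub-conditions used for decoding).
#' @return List with `samples` (matrix n_samples x voxels), `label`
#'   (character per sample) and `trial` (trial index per sample).
#' @export
extract_trial_samples <- function(bold, schedule, lag_tr = 2L,
                                  labels = c("1-action", "3-actions")) {
  if (is.vector(bold)) bold <- matrix(bold, nrow = 1L)
  n_tr <- ncol(bold)
  if (n_tr != schedule_n_tr(schedule)) stop("bold and schedule disagree")
  ev <- schedule$events
  fix <- ev[ev$kind == "fixation", , drop = FALSE]
  fix_tr <- unlist(lapply(seq_len(nrow(fix)), function(i) {
    start <- round(fix$onset[i] / TR_SECONDS) + 1L + lag_tr
    start:(start + round(fix$duration[i] / TR_SECONDS) - 1L)
  }))
  fix_tr <- fix_tr[fix_tr >= 1L & fix_tr <= n_tr]
  base <- rowMeans(bold[, fix_tr, drop = FALSE])
  if (any(base <= 0)) stop("non-positive fixation baseline")

  vids <- ev[ev$kind == "video" & ev$block_label %in% labels, , drop = FALSE]
  samp <- list(); lab <- character(0); trial <- integer(0)
  for (i in seq_len(nrow(vids))) {
    start <- round(vids$onset[i] / TR_SECONDS) + 1L + lag_tr
    trs <- start:(start + 1L)
    if (any(trs < 1L | trs > n_tr)) stop("lag pushes samples outside the run")
    for (t in trs) {
      samp[[length(samp) + 1L]] <- 100 * (bold[, t] - base) / base
      lab <- c(lab, vids$block_label[i])
      trial <- c(trial, i)
    }
  }
  list(samples = do.call(rbind, samp), label = lab, trial = trial)
}

#' Write / read a tidy PSC table
#'
#' The tab-delimited tidy layout (subject, roi, voxel, run, condition, psc)
#' is both the persistence format and the entry format for real per-voxel
#' PSC data.
#'
#' @param psc Array voxels x runs x conditions from [subject_psc()].
#' @param subject,roi Identifiers recorded in the table.
#' @param path Output path (TSV).
#' @export
write_psc_table <- function(psc, subject, roi, path) {
  dims <- dim(psc)
  tab <- data.frame(
    subject = subject, roi = roi,
    voxel = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
    run = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
    condition = rep(dimnames(psc)[[3]], each = dims[1] * dims[2]),
    psc = as.vector(psc)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psc_table
#' @return `read_psc_table()` returns the voxels x runs x conditions array.
#' @export
read_psc_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  conds <- unique(tab$condition)
  n_vox <- max(tab$voxel); n_run <- max(tab$run)
  out <- array(NA_real_, c(n_vox, n_run, length(conds)),
               dimnames = list(NULL, NULL, conds))
  out[cbind(tab$voxel, tab$run, match(tab$condition, conds))] <- tab$psc
  out
}
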