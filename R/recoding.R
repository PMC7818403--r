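# Cross-validated recoding of the four sub-conditions into preferred and
# non-preferred action / ball responses. Preference is decided on a
# selection subset of runs and the response attributed from the disjoint
# evaluation runs, which keeps the recoded contrast unbiased under the
# null; replicating over every selection subset and averaging gives the
# final per-voxel responses.

RECODED_LABELS <- c("PA", "nPA", "PB", "nPB")

#' Enumerate all selection/evaluation run splits
#'
#' @param n_runs Total number of runs.
#' @param k Number of selection runs (default 3 of 9, giving 84 splits).
#' @return List of splits, each `list(selection, evaluation)` of run
#'   indices, in deterministic lexicographic order.
#' @export
enumerate_splits <- function(n_runs = 9L, k = 3L) {
  if (k < 1L || k > n_runs - 1L) stop("k must be in 1..n_runs-1")
  sel <- utils::combn(n_runs, k)
  lapply(seq_len(ncol(sel)), function(j) {
    s <- sel[, j]
    list(selection = s, evaluation = setdiff(seq_len(n_runs), s))
  })
}

#' Recode one split
#'
#' For each voxel, the action sub-condition with the larger mean PSC over
#' the selection runs is the preferred action; PA and nPA are then the
#' evaluation-run means of the correspondingly labelled sub-conditions.
#' Balls are handled identically and independently. Exact ties in the
#' selection means are broken by a seeded coin flip and flagged.
#'
#' @param psc Array voxels x runs x 4 sub-conditions (see [subject_psc()]).
#' @param split One element of [enumerate_splits()]; `evaluate_on` lets the
#'   deliberately circular variant evaluate on the selection runs.
#' @param tie_seed Seed for tie-breaking.
#' @param evaluate_on `"evaluation"` (cross-validated, default) or
#'   `"selection"` (circular; used only to demonstrate selection bias).
#' @return Matrix voxels x 4 with columns PA, nPA, PB, nPB; attribute
#'   `ties` counts tie-broken voxels.
#' @export
recode_replication <- function(psc, split, tie_seed = 1L,
                               evaluate_on = c("evaluation", "selection")) {
  evaluate_on <- match.arg(evaluate_on)
  if (any(is.na(psc))) stop("missing PSC values")
  dims <- dim(psc)
  flat <- matrix(psc, dims[1], dims[2] * dims[3])
  # mean over a run subset, per condition, as one matrix product
  run_mean <- function(runs) {
    w <- matrix(0, dims[2] * dims[3], dims[3])
    for (cc in seq_len(dims[3])) w[(cc - 1L) * dims[2] + runs, cc] <- 1 / length(runs)
    flat %*% w
  }
  sel_mean <- run_mean(split$selection)
  eval_runs <- if (evaluate_on == "evaluation") split$evaluation
               else split$selection
  ev_mean <- run_mean(eval_runs)

  out <- matrix(NA_real_, nrow(sel_mean), 4L,
                dimnames = list(NULL, RECODED_LABELS))
  n_ties <- 0L
  for (f in 1:2) {                       # 1 = action pair, 2 = ball pair
    cols <- if (f == 1) 1:2 else 3:4
    d <- sel_mean[, cols[2]] - sel_mean[, cols[1]]
    tie <- d == 0
    if (any(tie)) {
      local_rng(tie_seed + f)
      d[tie] <- ifelse(stats::runif(sum(tie)) < 0.5, 1, -1)
      n_ties <- n_ties + sum(tie)
    }
    pref2 <- d > 0                       # TRUE: second sub-condition preferred
    out[, cols[1]] <- ifelse(pref2, ev_mean[, cols[2]], ev_mean[, cols[1]])
    out[, cols[2]] <- ifelse(pref2, ev_mean[, cols[1]], ev_mean[, cols[2]])
  }
  attr(out, "ties") <- n_ties
  out
}

#' Recode over all splits and average
#'
#' Replicates [recode_replication()] over every C(n_runs, k) split and
#' averages the attributed responses. Per-replication values are kept by
#' default; the refined group analysis needs them.
#'
#' @inheritParams recode_replication
#' @param k Number of selection runs.
#' @param keep_replications Keep the voxels x 4 x n_splits array?
#' @return List with `mean` (voxels x 4 matrix, columns PA, nPA, PB, nPB),
#'   `replications` (array or NULL), `k` and `n_splits`.
#' @export
recode_all <- function(psc, k = 3L, tie_seed = 1L, keep_replications = TRUE,
                       evaluate_on = c("evaluation", "selection")) {
  evaluate_on <- match.arg(evaluate_on)
  splits <- enumerate_splits(dim(psc)[2], k)
  n_vox <- dim(psc)[1]
  acc <- matrix(0, n_vox, 4L, dimnames = list(NULL, RECODED_LABELS))
  reps <- if (keep_replications)
    array(NA_real_, c(n_vox, 4L, length(splits)),
          dimnames = list(NULL, RECODED_LABELS, NULL)) else NULL
  for (j in seq_along(splits)) {
    r <- recode_replication(psc, splits[[j]], tie_seed = tie_seed + j,
                            evaluate_on = evaluate_on)
    attr(r, "ties") <- NULL
    acc <- acc + r
    if (keep_replications) reps[, , j] <- r
  }
  list(mean = acc / length(splits), replications = reps,
       k = k, n_splits = length(splits))
}

#' Write recoded responses as a tidy table
#' @param recoded Matrix voxels x 4 (`$mean` of [recode_all()]).
#' @param subject,roi Identifiers.
#' @param path Output TSV path.
#' @export
write_recoded_table <- function(recoded, subject, roi, path) {
  tab <- data.frame(subject = subject, roi = roi,
                    voxel = seq_len(nrow(recoded)),
                    PA = recoded[, "PA"], nPA = recoded[, "nPA"],
                    PB = recoded[, "PB"], nPB = recoded[, "nPB"])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
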