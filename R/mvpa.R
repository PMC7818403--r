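# Leave-one-run-out decoding of "1-action" vs "3-actions" from per-trial
# MR samples with a linear support vector machine.

#' Build leave-one-run-out decoding folds
#'
#' @param samples_by_run List (one per run) of [extract_trial_samples()]
#'   results restricted to the two action sub-conditions.
#' @param max_train_per_class Optional cap on training samples per class
#'   (first samples in run order are kept); sensitivity option for reading
#'   the training-set size as a total rather than per class.
#' @return List of folds; each holds `test_run`, `train` and `test`, both
#'   `list(x, y)` with x a samples x voxels matrix and y a factor.
#' @export
make_folds <- function(samples_by_run, max_train_per_class = NULL) {
  n_runs <- length(samples_by_run)
  if (n_runs < 2L) stop("need at least 2 runs")
  lapply(seq_len(n_runs), function(r) {
    train_idx <- setdiff(seq_len(n_runs), r)
    xtr <- do.call(rbind, lapply(samples_by_run[train_idx],
                                 function(s) s$samples))
    ytr <- unlist(lapply(samples_by_run[train_idx], function(s) s$label))
    if (!is.null(max_train_per_class)) {
      keep <- unlist(lapply(unique(ytr), function(cl)
        which(ytr == cl)[seq_len(min(max_train_per_class, sum(ytr == cl)))]))
      keep <- sort(keep)
      xtr <- xtr[keep, , drop = FALSE]
      ytr <- ytr[keep]
    }
    list(test_run = r,
         train = list(x = xtr, y = factor(ytr)),
         test = list(x = samples_by_run[[r]]$samples,
                     y = factor(samples_by_run[[r]]$label)))
  })
}

#' Train a linear SVM on one fold and score the held-out run
#'
#' @param fold One fold from [make_folds()].
#' @param cost SVM regularization constant.
#' @param scale Standardize features by training statistics?
#' @return Accuracy in percent on the test samples.
#' @export
train_eval_fold <- function(fold, cost = 1, scale = FALSE) {
  if (nlevels(droplevels(fold$train$y)) < 2L)
    stop("training set contains a single class")
  fit <- e1071::svm(x = fold$train$x, y = fold$train$y, kernel = "linear",
                    cost = cost, scale = scale)
  pred <- stats::predict(fit, fold$test$x)
  100 * mean(pred == fold$test$y)
}

#' Decode one subject: mean accuracy over the nine folds
#'
#' @param samples_by_run As for [make_folds()].
#' @inheritParams train_eval_fold
#' @return List with `fold_accuracy` (vector) and `accuracy` (mean, %).
#' @export
decode_subject <- function(samples_by_run, cost = 1, scale = FALSE) {
  folds <- make_folds(samples_by_run)
  acc <- vapply(folds, train_eval_fold, numeric(1), cost = cost,
                scale = scale)
  list(fold_accuracy = acc, accuracy = mean(acc))
}

#' Group-level decoding for one ROI
#'
#' Fold accuracies are averaged within subject, then across subjects; the
#' across-subject SD is reported alongside the 50% chance level.
#'
#' @param samples_by_subject List (one per subject) of per-run sample
#'   lists.
#' @inheritParams train_eval_fold
#' @return List with `subject_accuracy`, `mean`, `sd`, `chance`.
#' @export
decode_roi <- function(samples_by_subject, cost = 1, scale = FALSE) {
  acc <- vapply(samples_by_subject, function(s)
    decode_subject(s, cost = cost, scale = scale)$accuracy, numeric(1))
  list(subject_accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
       chance = 50)
}

#' Randomly permute the class labels of per-run samples
#'
#' Permutes labels uniformly within each run (keeping classes balanced per
#' run), severing any link between pattern and condition; used for
#' chance-level checks.
#'
#' @param samples_by_run Per-run sample list.
#' @param seed Integer seed.
#' @return The sample list with permuted labels.
#' @export
permute_labels <- function(samples_by_run, seed = 1L) {
  local_rng(seed)
  lapply(samples_by_run, function(s) {
    s$label <- sample(s$label)
    s
  })
}
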