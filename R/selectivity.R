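# Single-voxel selectivity for action numerosity: the dAction/dBall
# scatter, the below-diagonal proportion as the selectivity metric, its
# pairwise chi-square and paired-t comparisons, the subject-then-group
# shuffled null with 100-bin averaging, and the per-subject group analysis.

#' dAction / dBall scatter points
#'
#' dAction = PA - nPA and dBall = PB - nPB per voxel. In `group_average`
#' mode the recoded responses are first averaged across subjects voxel by
#' voxel (reducing the impact of unreliable voxels) and differenced once;
#' `per_subject` mode differences within each subject.
#'
#' @param recoded_by_subject List of voxels x 4 recoded matrices, one per
#'   subject (all the same voxel count).
#' @param mode `"group_average"` or `"per_subject"`.
#' @return For `group_average`, a data frame (voxel, dAction, dBall); for
#'   `per_subject`, a list of such data frames, one per subject.
#' @export
compute_scatter <- function(recoded_by_subject,
                            mode = c("group_average", "per_subject")) {
  mode <- match.arg(mode)
  nv <- vapply(recoded_by_subject, nrow, integer(1))
  if (length(unique(nv)) != 1L) stop("subjects have differing voxel counts")
  one <- function(m) data.frame(voxel = seq_len(nrow(m)),
                                dAction = m[, "PA"] - m[, "nPA"],
                                dBall = m[, "PB"] - m[, "nPB"])
  if (mode == "per_subject") return(lapply(recoded_by_subject, one))
  one(Reduce(`+`, recoded_by_subject) / length(recoded_by_subject))
}

#' Percentage of voxels below the diagonal of the dAction-dBall plane
#'
#' Strictly below: dAction > dBall; ties count as not below.
#'
#' @param points Data frame with `dAction` and `dBall`.
#' @return Percentage in [0, 100].
#' @export
prop_below_diagonal <- function(points) {
  if (!nrow(points)) stop("no points")
  100 * mean(points$dAction > points$dBall)
}

#' Paired t test of dAction against dBall across voxels
#'
#' One-sample t on the per-voxel differences; df = N - 1.
#'
#' @param points Data frame with `dAction` and `dBall`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
paired_t_voxels <- function(points) {
  d <- points$dAction - points$dBall
  if (length(d) < 2L) stop("need at least 2 voxels")
  if (stats::sd(d) == 0) stop("zero variance in differences")
  res <- stats::t.test(d)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Pearson chi-square comparing two below-diagonal percentages
#'
#' Reconstructs below/above counts by rounding percentage x N / 100 and
#' applies the Pearson test on the 2x2 table without continuity
#' correction.
#'
#' @param p1,p2 Percentages below the diagonal.
#' @param n1,n2 Voxel counts.
#' @return List with `chi2` (df = 1) and `p`.
#' @export
pairwise_chi2 <- function(p1, n1, p2, n2) {
  k1 <- round(p1 * n1 / 100); k2 <- round(p2 * n2 / 100)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2L)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margins")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), p = res$p.value)
}

#' Shuffled null distribution of the below-diagonal percentage
#'
#' Per subject and shuffle, the preferred / non-preferred labels are
#' randomly reassigned within each voxel's action pair and, independently,
#' within its ball pair (each swap with probability 1/2); the resulting
#' percentage of voxels below the diagonal is recorded. The per-subject
#' distributions over `n_shuffles` replications are binned (100 equal bins
#' on [0, 100]) and averaged bin per bin across subjects; the mean and SD
#' of that averaged distribution summarise the null. A full within-voxel
#' permutation of all four values is available via `granularity`.
#'
#' @param recoded_by_subject List of voxels x 4 recoded matrices.
#' @param n_shuffles Shuffles per subject.
#' @param n_bins Histogram bins spanning [0, 100].
#' @param seed Integer seed.
#' @param granularity `"pair_swap"` (default) or `"permute4"`.
#' @return List with `breaks`, `mid` (bin centres), `probability`
#'   (subject-averaged, sums to 1), `mean`, `sd`, `n_shuffles`, and
#'   `subject_props` (n_shuffles x n_subjects matrix of raw percentages).
#' @export
shuffle_null <- function(recoded_by_subject, n_shuffles = 10000L,
                         n_bins = 100L, seed = 1L,
                         granularity = c("pair_swap", "permute4")) {
  granularity <- match.arg(granularity)
  local_rng(seed)
  breaks <- seq(0, 100, length.out = n_bins + 1L)
  props <- sapply(recoded_by_subject, function(m) {
    shuffle_props(m, n_shuffles, granularity)
  })
  dens <- apply(props, 2, function(p) {
    h <- graphics::hist(p, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)
    h$counts / length(p)
  })
  prob <- rowMeans(dens)
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mu <- sum(prob * mid)
  sdv <- sqrt(sum(prob * (mid - mu)^2))
  list(breaks = breaks, mid = mid, probability = prob, mean = mu, sd = sdv,
       n_shuffles = n_shuffles, subject_props = props)
}

# Vector of n_shuffles below-diagonal percentages for one subject's
# recoded matrix under label reassignment.
shuffle_props <- function(m, n_shuffles, granularity) {
  dA <- m[, "PA"] - m[, "nPA"]
  dB <- m[, "PB"] - m[, "nPB"]
  n_vox <- length(dA)
  if (granularity == "pair_swap") {
    # swapping labels within a pair flips the sign of the difference
    sA <- matrix(sample(c(-1, 1), n_shuffles * n_vox, replace = TRUE),
                 n_shuffles, n_vox)
    sB <- matrix(sample(c(-1, 1), n_shuffles * n_vox, replace = TRUE),
                 n_shuffles, n_vox)
    dAs <- sweep(sA, 2, dA, `*`)
    dBs <- sweep(sB, 2, dB, `*`)
    return(100 * rowMeans(dAs > dBs))
  }
  # permute4: all 4! arrangements of the voxel's four values over the
  # four labels, drawn uniformly per voxel per shuffle
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4L), ,
                 drop = FALSE]
  vals <- m[, RECODED_LABELS, drop = FALSE]
  vapply(seq_len(n_shuffles), function(s) {
    pick <- perms[sample.int(nrow(perms), n_vox, replace = TRUE), ,
                  drop = FALSE]
    idx <- cbind(rep(seq_len(n_vox), 4L), as.vector(pick))
    v <- matrix(vals[idx], n_vox, 4L)
    100 * mean((v[, 1] - v[, 2]) > (v[, 3] - v[, 4]))
  }, numeric(1))
}

#' Distance of an observed percentage from the shuffled null, in SD units
#'
#' @param actual_prop Observed below-diagonal percentage.
#' @param null A [shuffle_null()] result, or any list with `mean` and `sd`.
#' @return (actual - null mean) / null SD.
#' @export
sd_distance <- function(actual_prop, null) {
  if (null$sd <= 0) stop("null SD must be positive")
  (actual_prop - null$mean) / null$sd
}

#' Group analysis of the below-diagonal proportion
#'
#' Computes the below-diagonal percentage per subject — from the
#' replication-averaged recoded responses (standard) or as the average of
#' per-replication percentages (refined; reduces the impact of unreliable
#' voxels) — then the group mean, SD, and a one-tailed t test against 50%.
#'
#' @param recoded_by_subject List of [recode_all()] results (the full list,
#'   not just `$mean`; the refined variant needs `$replications`).
#' @param refined Use the per-replication variant?
#' @return List with `subject_props`, `mean`, `sd`, `t`, `df`, `p`
#'   (one-tailed, alternative greater than 50%).
#' @export
group_prop_analysis <- function(recoded_by_subject, refined = FALSE) {
  if (length(recoded_by_subject) < 2L) stop("need at least 2 subjects")
  props <- vapply(recoded_by_subject, function(rec) {
    if (refined) {
      if (is.null(rec$replications))
        stop("refined analysis needs per-replication recodings")
      reps <- rec$replications
      mean(apply(reps, 3, function(m)
        100 * mean((m[, "PA"] - m[, "nPA"]) > (m[, "PB"] - m[, "nPB"]))))
    } else {
      prop_below_diagonal(compute_scatter(list(rec$mean)))
    }
  }, numeric(1))
  n <- length(props)
  if (stats::sd(props) == 0) {
    # degenerate but well-defined: no spread means no evidence either way
    # unless the common value itself differs from 50
    t <- if (mean(props) == 50) 0 else sign(mean(props) - 50) * Inf
    p <- if (mean(props) > 50) 0 else 1
    if (t == 0) p <- 0.5
    return(list(subject_props = props, mean = mean(props), sd = 0,
                t = t, df = n - 1L, p = p))
  }
  tt <- stats::t.test(props, mu = 50, alternative = "greater")
  list(subject_props = props, mean = mean(props), sd = stats::sd(props),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Paired t test of per-subject proportions between two ROIs
#'
#' @param props_a,props_b Per-subject percentages (same subject order).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
paired_t_rois <- function(props_a, props_b) {
  res <- stats::t.test(props_a, props_b, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
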