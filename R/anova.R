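# ROI-level univariate analysis: per-subject ROI averages of the recoded
# responses, 2x2 repeated-measures ANOVA (attended feature x preference),
# and Holm step-down correction across ROIs.

#' Average recoded responses over the voxels of an ROI
#'
#' @param recoded_by_subject List (one element per subject) of voxels x 4
#'   recoded matrices.
#' @return Matrix subjects x 4 with columns PA, nPA, PB, nPB.
#' @export
roi_average <- function(recoded_by_subject) {
  if (!length(recoded_by_subject)) stop("no subjects")
  out <- t(vapply(recoded_by_subject, colMeans, numeric(4L)))
  colnames(out) <- RECODED_LABELS
  out
}

#' Two-way repeated-measures ANOVA for a 2x2 within-subject design
#'
#' Factors are attended feature (action vs ball) and preference (preferred
#' vs non-preferred). With two levels per factor each effect reduces to a
#' per-subject contrast tested against its own subject-by-effect
#' variability, giving F with df (1, n-1) — the classical within-subject
#' partition; no sphericity correction is needed for two-level factors.
#'
#' @param data Matrix subjects x 4, columns PA, nPA, PB, nPB.
#' @return Data frame with one row per effect (`feature`, `preference`,
#'   `interaction`): F, df1, df2, p.
#' @export
rm_anova_2x2 <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 3L) stop("need at least 3 subjects")
  if (any(is.na(data))) stop("missing cells")
  n <- nrow(data)
  contrasts <- list(
    feature = c(0.5, 0.5, -0.5, -0.5),        # (PA+nPA)/2 - (PB+nPB)/2
    preference = c(0.5, -0.5, 0.5, -0.5),     # (PA+PB)/2 - (nPA+nPB)/2
    interaction = c(0.5, -0.5, -0.5, 0.5)     # [(PA-nPA) - (PB-nPB)]/2
  )
  rows <- lapply(names(contrasts), function(eff) {
    cvec <- data %*% contrasts[[eff]]
    ss_effect <- n * mean(cvec)^2
    # an exactly null effect has F = 0 even when the error term is also
    # degenerate (zero-noise synthetic data)
    f <- if (ss_effect == 0) 0 else ss_effect / stats::var(cvec)[1]
    data.frame(effect = eff, F = f, df1 = 1L, df2 = n - 1L,
               p = stats::pf(f, 1, n - 1, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Holm step-down multiple-comparison correction
#'
#' Compares the k-th smallest p value with alpha/(n-k+1), stopping at the
#' first failure; every test before the stop is flagged significant.
#'
#' @param p_values Numeric vector of p values in [0, 1].
#' @param alpha Family-wise error level.
#' @return Data frame in the input order with `p`, `rank`, `threshold`
#'   (alpha/(n-k+1) for the test's rank) and logical `significant`.
#' @export
holm_correct <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  n <- length(p_values)
  ord <- order(p_values)
  thresh <- alpha / (n - seq_len(n) + 1)
  sig_sorted <- logical(n)
  for (k in seq_len(n)) {
    if (p_values[ord[k]] < thresh[k]) sig_sorted[k] <- TRUE else break
  }
  out <- data.frame(p = p_values, rank = NA_integer_,
                    threshold = NA_real_, significant = NA)
  out$rank[ord] <- seq_len(n)
  out$threshold[ord] <- thresh
  out$significant[ord] <- sig_sorted
  out
}

#' ROI-by-effect ANOVA table with Holm correction per effect family
#'
#' Runs [rm_anova_2x2()] per ROI and applies [holm_correct()] across ROIs
#' separately within each effect (feature, preference, interaction),
#' mirroring correction over n = 8 ROIs.
#'
#' @param roi_means Named list: per ROI, a subjects x 4 matrix from
#'   [roi_average()].
#' @param alpha Family-wise error level.
#' @return Data frame: roi, effect, F, df1, df2, p, holm_significant.
#' @export
anova_table <- function(roi_means, alpha = 0.05) {
  per_roi <- lapply(names(roi_means), function(roi) {
    res <- rm_anova_2x2(roi_means[[roi]])
    res$roi <- roi
    res
  })
  tab <- do.call(rbind, per_roi)
  tab$holm_significant <- NA
  for (eff in unique(tab$effect)) {
    sel <- tab$effect == eff
    tab$holm_significant[sel] <- holm_correct(tab$p[sel], alpha)$significant
  }
  tab[, c("roi", "effect", "F", "df1", "df2", "p", "holm_significant")]
}
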