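test_that("ROI averaging reduces voxel tables to per-subject quadruples", {
  recs <- null_recoded(30, 21, seed = 1)
  m <- roi_average(recs)
  expect_equal(dim(m), c(21L, 4L))
  expect_equal(colnames(m), c("PA", "nPA", "PB", "nPB"))
  # brute-force recomputation
  expect_equal(unname(m[3, ]), unname(apply(recs[[3]], 2, mean)))

  # identical voxels collapse to the common value
  same <- matrix(rep(c(1, 2, 3, 4), each = 10), 10, 4,
                 dimnames = list(NULL, c("PA", "nPA", "PB", "nPB")))
  expect_equal(unname(roi_average(list(same, same))),
               matrix(c(1, 1, 2, 2, 3, 3, 4, 4), 2))
  expect_error(roi_average(list()), "no subjects")
})

test_that("the 2x2 repeated-measures ANOVA matches aov and its exact cases", {
  # df (1, n-1) for every effect with 21 subjects
  res <- rm_anova_2x2(roi_average(null_recoded(10, 21, seed = 2)))
  expect_equal(res$df1, rep(1L, 3))
  expect_equal(res$df2, rep(20L, 3))

  # pure preference effect with zero subject noise: interaction F = 0
  # (dyadic values keep the zero contrasts exact in floating point)
  a <- 0.5; b <- 0.25
  exact <- matrix(rep(c(a + b, a, a + b, a), each = 6), 6, 4,
                  dimnames = list(NULL, c("PA", "nPA", "PB", "nPB")))
  res2 <- rm_anova_2x2(exact)
  expect_equal(res2$F[res2$effect == "interaction"], 0)
  expect_equal(res2$F[res2$effect == "feature"], 0)

  # independent oracle: stats::aov with the within-subject error strata
  for (seed in 1:4) {
    set.seed(seed)
    dat <- matrix(rnorm(6 * 4), 6, 4,
                  dimnames = list(NULL, c("PA", "nPA", "PB", "nPB")))
    mine <- rm_anova_2x2(dat)
    long <- data.frame(
      y = as.vector(dat),
      subject = factor(rep(1:6, 4)),
      feature = factor(rep(c("action", "action", "ball", "ball"), each = 6)),
      pref = factor(rep(c("p", "n", "p", "n"), each = 6)))
    fit <- summary(aov(y ~ feature * pref + Error(subject / (feature * pref)),
                       data = long))
    get_f <- function(stratum, term) {
      tab <- fit[[stratum]][[1]]
      tab[trimws(rownames(tab)) == term, "F value"]
    }
    expect_equal(mine$F[mine$effect == "feature"],
                 get_f("Error: subject:feature", "feature"), tolerance = 1e-10)
    expect_equal(mine$F[mine$effect == "preference"],
                 get_f("Error: subject:pref", "pref"), tolerance = 1e-10)
    expect_equal(mine$F[mine$effect == "interaction"],
                 get_f("Error: subject:feature:pref", "feature:pref"),
                 tolerance = 1e-10)
  }

  expect_error(rm_anova_2x2(exact[1:2, ]), "3 subjects")
  bad <- exact; bad[1, 1] <- NA
  expect_error(rm_anova_2x2(bad), "missing")
})

test_that("Holm's step-down rule flags a prefix of the sorted p values", {
  # threshold for the smallest of 8 p values is 0.05/8
  h <- holm_correct(rep(0.5, 8))
  expect_equal(h$threshold[h$rank == 1], 0.05 / 8)
  expect_false(any(holm_correct(rep(1, 8))$significant))

  p <- c(0.001, 0.002, 0.03, 0.04, 0.05, 0.2, 0.5, 0.9)
  h2 <- holm_correct(p)
  # brute-force application of the stopping rule
  expected <- logical(8); thr <- 0.05 / (8 - seq_len(8) + 1)
  for (k in 1:8) { if (p[k] < thr[k]) expected[k] <- TRUE else break }
  expect_equal(h2$significant, expected)
  # flags form a prefix of the sorted order
  expect_true(all(diff(h2$significant[order(h2$p)]) <= 0))

  # monotonicity: lowering one p value never removes another's flag
  set.seed(9)
  for (i in 1:20) {
    p0 <- runif(8)
    f0 <- holm_correct(p0)$significant
    j <- sample(8, 1)
    p1 <- p0; p1[j] <- p0[j] / 10
    f1 <- holm_correct(p1)$significant
    expect_true(all(f1[f0 & seq_len(8) != j] >= f0[f0 & seq_len(8) != j]))
  }
  expect_error(holm_correct(c(0.5, 1.2)), "0, 1")
})

test_that("the ROI table corrects each effect family across ROIs", {
  rois <- list(A = roi_average(null_recoded(10, 8, seed = 5)),
               B = roi_average(null_recoded(10, 8, seed = 6)))
  tab <- anova_table(rois)
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$effect), c("feature", "preference", "interaction"))
  for (eff in unique(tab$effect)) {
    sel <- tab$effect == eff
    expect_equal(tab$holm_significant[sel],
                 holm_correct(tab$p[sel])$significant)
  }
})
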