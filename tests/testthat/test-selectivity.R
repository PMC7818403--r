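mk_rec <- function(PA, nPA, PB, nPB) {
  matrix(c(PA, nPA, PB, nPB), ncol = 4,
         dimnames = list(NULL, c("PA", "nPA", "PB", "nPB")))
}

test_that("scatter points are recoded differences, group-averaged first", {
  one <- mk_rec(1, 0.2, 0.5, 0.4)
  pts <- compute_scatter(list(one))
  expect_equal(pts$dAction, 0.8)
  expect_equal(pts$dBall, 0.1)

  # averaging across subjects commutes with differencing
  two <- mk_rec(0.4, 0.1, 0.2, 0.6)
  g <- compute_scatter(list(one, two))
  expect_equal(g$dAction, ((1 + 0.4) / 2 - (0.2 + 0.1) / 2))
  expect_equal(g$dBall, ((0.5 + 0.2) / 2 - (0.4 + 0.6) / 2))
  per <- compute_scatter(list(one, two), mode = "per_subject")
  expect_length(per, 2L)
  expect_equal(per[[2]]$dAction, 0.3)

  expect_error(compute_scatter(list(one, mk_rec(c(1, 2), c(0, 0), c(0, 0), c(0, 0)))),
               "differing voxel counts")
})

test_that("the below-diagonal percentage is strict and symmetric", {
  pts <- data.frame(dAction = c(1, 2, 3), dBall = c(0, 1, 2))
  expect_equal(prop_below_diagonal(pts), 100)
  # ties count as not below
  expect_equal(prop_below_diagonal(data.frame(dAction = 1, dBall = 1)), 0)
  # mirroring across the diagonal complements the percentage
  set.seed(4)
  rnd <- data.frame(dAction = rnorm(101), dBall = rnorm(101))
  mir <- data.frame(dAction = rnd$dBall, dBall = rnd$dAction)
  expect_equal(prop_below_diagonal(rnd) + prop_below_diagonal(mir), 100)
  expect_error(prop_below_diagonal(rnd[0, ]), "no points")
})

test_that("the voxel-wise paired t matches the closed-form statistic", {
  set.seed(5)
  pts <- data.frame(dAction = rnorm(449), dBall = rnorm(449))
  res <- paired_t_voxels(pts)
  expect_equal(res$df, 448)
  d <- pts$dAction - pts$dBall
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_manual, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_manual), 448), tolerance = 1e-10)

  # symmetric paired constants cancel exactly
  sym <- data.frame(dAction = c(1, -1, 2, -2), dBall = c(0, 0, 0, 0))
  expect_equal(paired_t_voxels(sym)$t, 0)
  expect_error(paired_t_voxels(data.frame(dAction = c(1, 1), dBall = c(0, 0))),
               "zero variance")
})

test_that("the two-proportion chi-square equals the generic Pearson statistic", {
  expect_equal(pairwise_chi2(60, 100, 60, 100)$chi2, 0)
  set.seed(6)
  for (i in 1:100) {
    n1 <- sample(50:500, 1); n2 <- sample(50:500, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    res <- pairwise_chi2(100 * k1 / n1, n1, 100 * k2 / n2, n2)
    tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2)
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    chi_manual <- sum((tab - exp_tab)^2 / exp_tab)
    expect_equal(res$chi2, chi_manual, tolerance = 1e-10)
  }
  expect_error(pairwise_chi2(0, 100, 0, 100), "degenerate")
})

test_that("shuffling recenters any ROI at 50% with binomial spread", {
  recs <- null_recoded(150, 5, seed = 7)
  # inject strong selectivity: the null must not care
  recs <- lapply(recs, function(m) { m[, "PA"] <- m[, "PA"] + 2; m })
  nl <- shuffle_null(recs, n_shuffles = 2000, seed = 8)
  expect_equal(sum(nl$probability), 1)
  expect_lt(abs(nl$mean - 50), 0.5)
  expect_lt(abs(nl$sd - 100 * sqrt(0.25 / 150)), 0.5)
  expect_equal(length(nl$probability), 100L)

  # seeded reproducibility
  nl2 <- shuffle_null(recs, n_shuffles = 2000, seed = 8)
  expect_identical(nl$probability, nl2$probability)

  # per-subject shuffled distributions look normal at realistic voxel counts
  props <- nl$subject_props[, 1]
  sk <- mean((props - mean(props))^3) / sd(props)^3
  ku <- mean((props - mean(props))^4) / sd(props)^4 - 3
  expect_lt(abs(sk), 0.2)
  expect_lt(abs(ku), 0.4)

  # full 4-value permutation variant is also centred at 50
  nl4 <- shuffle_null(recs[1:2], n_shuffles = 300, seed = 9,
                      granularity = "permute4")
  expect_lt(abs(nl4$mean - 50), 2)
})

test_that("SD distance standardises against the shuffled null", {
  expect_equal(sd_distance(50, list(mean = 50, sd = 2)), 0)
  expect_equal(sd_distance(56, list(mean = 50, sd = 2)), 3)
  expect_error(sd_distance(50, list(mean = 50, sd = 0)), "positive")
})

test_that("group proportions: per-subject t tests and the refined variant", {
  # all subjects exactly at 50%: t = 0
  rec50 <- lapply(1:5, function(s)
    list(mean = mk_rec(c(1, 0), c(0, 1), c(0, 0), c(0, 0)),
         replications = NULL))
  g <- group_prop_analysis(rec50)
  expect_equal(g$mean, 50)
  expect_equal(g$t, 0)
  expect_equal(g$df, 4L)

  # 21 subjects give df 20; refined variant shrinks the across-subject SD
  set.seed(10)
  recs <- lapply(1:21, function(s) {
    psc <- null_psc(40, seed = 100 + s)
    psc[, , "3-actions"] <- psc[, , "3-actions"] + 0.4
    recode_all(psc, k = 3)
  })
  std <- group_prop_analysis(recs, refined = FALSE)
  ref <- group_prop_analysis(recs, refined = TRUE)
  expect_equal(std$df, 20L)
  expect_equal(ref$df, 20L)
  expect_lt(ref$sd, std$sd)

  # paired comparison between ROIs
  pt <- paired_t_rois(std$subject_props, ref$subject_props)
  expect_equal(pt$df, 20L)
  expect_error(group_prop_analysis(recs[1]), "2 subjects")
})
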