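test_that("AUC equals pairwise concordance, with tie and error handling", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "single class")

  set.seed(81)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
    scores <- round(stats::rnorm(n), 1)  # rounding forces ties
    expect_equal(roc_auc(labels, scores)$auc, oracle_auc(labels, scores))
  }
})

test_that("ROC curves are monotone and span the unit square", {
  set.seed(82)
  r <- roc_auc(rep(c(0, 1), each = 20), stats::rnorm(40))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_equal(range(r$curve$fpr), c(0, 1))
  expect_equal(range(r$curve$tpr), c(0, 1))
})

test_that("DeLong's test matches the structural-components loop oracle", {
  set.seed(83)
  for (rep in 1:5) {
    labels <- rep(c(1, 0), each = 4)
    a <- stats::rnorm(8) + labels
    b <- 0.6 * a + stats::rnorm(8)
    got <- delong_test(roc_auc(labels, a), roc_auc(labels, b))
    expect_equal(got$p_value, oracle_delong(labels, a, b), tolerance = 1e-10)
  }
})

test_that("DeLong degeneracy and power behave as specified", {
  labels <- rep(c(1, 0), 10)
  s <- stats::rnorm(20)
  r <- roc_auc(labels, s)
  same <- delong_test(r, r)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  expect_error(delong_test(r, roc_auc(labels[-1], s[-1])), "paired")

  set.seed(84)
  labels2 <- rep(c(1, 0), each = 200)
  strong <- stats::rnorm(400) + 2.3 * labels2   # AUC ~ 0.95
  weak <- stats::rnorm(400) + 0.18 * labels2    # AUC ~ 0.55
  dl <- delong_test(roc_auc(labels2, strong), roc_auc(labels2, weak))
  expect_lt(dl$p_value, 0.001)
})

test_that("p-value matrices are symmetric with unit diagonal and display floor", {
  labels <- rep(c(1, 0), each = 6)
  s <- stats::rnorm(12)
  r <- roc_auc(labels, s)
  pm <- pvalue_matrix(list(I = r, II = r))
  expect_equal(pm$p_values[1, 2], 1)

  set.seed(85)
  rocs <- lapply(1:4, function(i) roc_auc(labels, stats::rnorm(12) + labels))
  pm2 <- pvalue_matrix(rocs)
  expect_identical(pm2$p_values, t(pm2$p_values))
  expect_equal(diag(pm2$p_values), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(pm2$p_values >= 0 & pm2$p_values <= 1))
  expect_identical(pm2$display, pmax(pm2$p_values, 1e-14))
})

test_that("subset partition reproduces the documented size rule", {
  big <- partition_dataset(2602, 5, seed = 1)
  expect_equal(big$sizes, c(520, 520, 520, 520, 522), ignore_attr = TRUE)
  expect_equal(partition_dataset(5, 5)$sizes, rep(1, 5), ignore_attr = TRUE)
  expect_equal(partition_dataset(12, 5)$sizes, c(2, 2, 2, 2, 4),
               ignore_attr = TRUE)
  expect_error(partition_dataset(3, 5), "fewer")
  # disjoint and exhaustive
  expect_equal(tabulate(big$assignments, 5), big$sizes, ignore_attr = TRUE)
  # seeded determinism
  expect_identical(partition_dataset(100, 5, seed = 9)$assignments,
                   partition_dataset(100, 5, seed = 9)$assignments)
  expect_false(identical(partition_dataset(100, 5, seed = 9)$assignments,
                         partition_dataset(100, 5, seed = 10)$assignments))
})

test_that("repetition averaging is the per-nodule arithmetic mean", {
  tab <- cbind(rep(0.3, 4), rep(0.3, 4), rep(0.3, 4))
  expect_equal(repetition_average(tab), tab[, 1])
  expect_equal(repetition_average(matrix(c(0.2, 0.4, 0.6, 0.8, 1.0), 1)), 0.6)
  expect_error(repetition_average(matrix(c(0.2, NA), 1)), "missing")
})

test_that("paired t-tests across subsets match a hand computation", {
  a <- c(0.90, 0.91, 0.89, 0.92, 0.90)
  b <- c(0.70, 0.72, 0.69, 0.71, 0.70)
  res <- paired_ttest_regions(cbind(A = a, B = b))
  d <- a - b
  tstat <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(res$p_values[1, 2], 2 * stats::pt(-abs(tstat), df = 4))
  expect_lt(res$p_values[1, 2], 0.01)
  expect_equal(res$means, c(A = mean(a), B = mean(b)))
  expect_equal(res$sds, c(A = stats::sd(a), B = stats::sd(b)))

  same <- paired_ttest_regions(cbind(a, a))
  expect_equal(same$p_values[1, 2], 1)          # self-comparison convention
  expect_true(same$degenerate[1, 2])
  expect_error(paired_ttest_regions(matrix(0.9, 1, 3)), "2 subsets")
})

test_that("Dice matches its definition and conventions", {
  a <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 2, 3)
  b <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE), 2, 3)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, !a), 0)
  expect_equal(dice(a, b), 2 * 3 / (4 + 5))
  expect_equal(dice(a, b), dice(b, a))
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice(a, matrix(TRUE, 3, 2)), "dimensions")
  # |A| = 4, |B| = 6, |A intersect B| = 3 -> 0.6
  x <- matrix(FALSE, 4, 4); x[1:4] <- TRUE
  y <- matrix(FALSE, 4, 4); y[2:7] <- TRUE
  expect_equal(dice(x, y), 0.6)
})
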