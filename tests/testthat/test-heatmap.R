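test_that("all-zero feature maps give a zero CAM with zero score", {
  out <- fake_output(array(0, c(3, 3, 2)), matrix(0.5, 2, 2))
  cam <- compute_cam(out, 2L)
  expect_true(all(cam$values == 0))
  expect_equal(cam$source_score, 0)
})

test_that("closed form: K = 1, omega = 2, g constant 3 on a 2x2 grid", {
  out <- fake_output(array(3, c(2, 2, 1)), matrix(c(0, 2), 1, 2))
  cam <- compute_cam(out, 2L)
  expect_true(all(cam$values == 6))
  expect_equal(cam$source_score, 24)
  expect_equal(sum(cam$values), cam$source_score)
})

test_that("CAM matches the triple-loop oracle and the sum-to-score identity", {
  set.seed(41)
  for (rep in 1:5) {
    feat <- array(stats::rnorm(3 * 3 * 2), c(3, 3, 2))
    w <- matrix(stats::rnorm(4), 2, 2)
    out <- fake_output(feat, w)
    for (i in 1:2) {
      cam <- compute_cam(out, i)
      expect_equal(cam$values, oracle_cam(feat, w[, i]), tolerance = 1e-12)
      expect_lt(abs(sum(cam$values) - out$class_scores[i]), 1e-5)
    }
  }
  expect_error(compute_cam(fake_output(array(0, c(2, 2, 1)), matrix(0, 1, 2)), 3L),
               "class index")
})

test_that("doubling the head weights doubles the CAM pointwise", {
  set.seed(42)
  feat <- array(stats::rnorm(18), c(3, 3, 2))
  w <- matrix(stats::rnorm(4), 2, 2)
  c1 <- compute_cam(fake_output(feat, w), 2L)
  c2 <- compute_cam(fake_output(feat, 2 * w), 2L)
  expect_equal(c2$values, 2 * c1$values, tolerance = 1e-12)
})

test_that("bilinear upsampling preserves constants, identity, bounds and order", {
  cam <- compute_cam(fake_output(array(1.5, c(2, 2, 1)), matrix(1, 1, 2)), 1L)
  up <- upsample_cam(cam, 8L)
  expect_true(all(abs(up$upsampled - 1.5) < 1e-12))

  m <- matrix(c(0, 0, 1, 1), 2, 2)  # [[0,1],[0,1]] row-wise
  cam2 <- compute_cam(fake_output(array(m, c(2, 2, 1)), matrix(1, 1, 2)), 1L)
  up2 <- upsample_cam(cam2, c(4L, 4L))$upsampled
  for (r in 1:4) expect_true(all(diff(up2[r, ]) >= 0))  # monotone along rows
  expect_gte(min(up2), min(m))
  expect_lte(max(up2), max(m))

  same <- upsample_cam(cam2, c(2L, 2L))$upsampled
  expect_equal(same, cam2$values, tolerance = 1e-12)
  expect_error(upsample_cam(cam2, 1L), "at least")
})

test_that("malignancy heat map is normalized, probability-bounded and validated", {
  set.seed(43)
  feat <- array(stats::rnorm(32), c(4, 4, 2))
  cam <- compute_cam(fake_output(feat, matrix(stats::rnorm(4), 2, 2)), 2L)
  hm0 <- malignancy_heatmap(cam, 0)
  expect_true(all(hm0$values == 0))
  hm <- malignancy_heatmap(cam, 0.5)
  expect_equal(max(hm$values), 0.5, tolerance = 1e-12)
  expect_true(all(hm$values >= 0))
  expect_lte(max(hm$values), hm$p_malignant + 1e-9)
  expect_error(malignancy_heatmap(cam, 1.2), "p_malignant")
  # an all-negative CAM clamps to a zero map rather than dividing by zero
  neg <- compute_cam(fake_output(array(1, c(2, 2, 1)), matrix(-1, 1, 2)), 1L)
  expect_true(all(malignancy_heatmap(neg, 0.9)$values == 0))
})

test_that("peak heat follows the predicted malignancy probability ordering", {
  set.seed(44)
  feat <- array(abs(stats::rnorm(32)), c(4, 4, 2))
  cam <- compute_cam(fake_output(feat, matrix(abs(stats::rnorm(4)), 2, 2)), 2L)
  low <- malignancy_heatmap(cam, 0.2907)
  high <- malignancy_heatmap(cam, 0.9382)
  expect_lt(max(low$values), max(high$values))
  # the rendered overlays differ accordingly: red dominates blue only for
  # the high-probability map
  r_low <- render_heatmap(low, "malignancy")
  r_high <- render_heatmap(high, "malignancy")
  warmth <- function(rgb) mean(rgb[, , 1]) - mean(rgb[, , 3])
  expect_lt(warmth(r_low), warmth(r_high))
})

test_that("rendering is rank-preserving and handles the zero map", {
  zero <- render_heatmap(matrix(0, 4, 4), "malignancy")
  expect_equal(length(unique(as.vector(zero[, , 1]))), 1)  # uniform color
  expect_gt(zero[1, 1, 3], zero[1, 1, 1])                  # blue end

  set.seed(45)
  v <- matrix(stats::runif(64), 8, 8)
  for (mode in c("conventional", "malignancy")) {
    rgb <- render_heatmap(v, mode)
    warmth <- rgb[, , 1] - rgb[, , 3]
    o <- order(v)
    expect_true(all(diff(warmth[o]) > -1e-9))  # warmer never cools as heat rises
  }
  img <- matrix(0.5, 8, 8)
  ov <- render_heatmap(v, "malignancy", image = img, alpha = 0.4)
  expect_identical(dim(ov), c(8L, 8L, 3L))
  expect_true(all(ov >= 0 & ov <= 1))
})
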