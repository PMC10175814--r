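# ROC/AUC, DeLong's paired test, subset partitioning, repetition averaging,
# paired t-tests across subsets, and the Dice coefficient.

#' ROC curve and AUC
#'
#' The AUC equals the Mann-Whitney concordance probability, with ties
#' counted as 1/2 (computed via midranks).
#'
#' @param labels Binary vector (0/1, logical, or `"benign"`/`"malignant"`);
#'   1/malignant is the positive class.
#' @param scores Numeric scores, higher = more positive.
#' @return Object of class `roc_result`: `auc`, `curve` (data frame of FPR,
#'   TPR), plus the retained `scores` and `labels` for paired testing.
#' @export
roc_auc <- function(labels, scores) {
  labels <- normalize_labels(labels)
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC is undefined with a single class", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / n0, numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(auc = auc, curve = curve, scores = scores, labels = labels),
            class = "roc_result")
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "malignant")
  } else {
    as.integer(labels != 0)
  }
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

# Placement values (structural components) of a score vector:
# V10[i] = mean_j psi(x_i, y_j) over negatives, V01[j] = mean_i psi(x_i, y_j)
# over positives, with psi = 1, 1/2, 0 for concordant / tied / discordant.
placement_values <- function(scores, labels) {
  xs <- scores[labels == 1L]
  ys <- scores[labels == 0L]
  psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong's test for two correlated AUCs
#'
#' Both ROC results must come from the same cases (paired design). The
#' variance of the AUC difference is estimated from the covariance of the
#' structural components; the z statistic is referred to a standard normal,
#' two-sided. If the estimated variance of the difference is zero (for
#' example identical score vectors, or perfect separation in both), the test
#' is degenerate and `p = 1` is returned with `degenerate = TRUE`.
#'
#' @param roc_a,roc_b [roc_auc()] results on identical labels.
#' @return List with `p_value`, `z`, `auc_a`, `auc_b`, `var_diff`,
#'   `degenerate`.
#' @export
delong_test <- function(roc_a, roc_b) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (length(roc_a$labels) != length(roc_b$labels) ||
      any(roc_a$labels != roc_b$labels)) {
    stop("DeLong's test requires paired ROCs on identical cases", call. = FALSE)
  }
  pa <- placement_values(roc_a$scores, roc_a$labels)
  pb <- placement_values(roc_b$scores, roc_b$labels)
  m <- length(pa$v10)   # positives
  n <- length(pa$v01)   # negatives
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (!is.finite(var_diff) || var_diff <= 0) {
    return(list(p_value = 1, z = 0, auc_a = pa$auc, auc_b = pb$auc,
                var_diff = max(var_diff, 0), degenerate = TRUE))
  }
  z <- d / sqrt(var_diff)
  list(p_value = 2 * stats::pnorm(-abs(z)), z = z,
       auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
       degenerate = FALSE)
}

#' Pairwise DeLong p-value matrix
#'
#' @param rocs Named list of paired [roc_auc()] results (e.g. regions I-V).
#' @param display_floor P-values below this are floored in the `display`
#'   copy only; raw values are retained in `p_values`.
#' @return Object of class `comparison_matrix`: `p_values` (raw, symmetric,
#'   diagonal 1), `display` (floored) and `display_floor`.
#' @export
pvalue_matrix <- function(rocs, display_floor = 1e-14) {
  stopifnot(length(rocs) >= 2)
  k <- length(rocs)
  nm <- names(rocs)
  if (is.null(nm)) nm <- as.character(utils::as.roman(seq_len(k)))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      p[i, j] <- p[j, i] <- delong_test(rocs[[i]], rocs[[j]])$p_value
    }
  }
  structure(list(p_values = p, display = pmax(p, display_floor),
                 display_floor = display_floor),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix> pairwise p-values (displayed floor %g)\n",
              x$display_floor))
  print(signif(x$display, 3))
  invisible(x)
}

#' Random partition into k subsets
#'
#' A seeded random permutation is split into k blocks of `floor(n/k)` items;
#' the remainder is appended to the final subset (so n = 2602, k = 5 gives
#' sizes 520, 520, 520, 520, 522).
#'
#' @param n Number of items, or a dataset whose length is used.
#' @param k Number of subsets.
#' @param seed Integer seed.
#' @return Object of class `subset_split`: `assignments` (subset index per
#'   item) and `sizes`.
#' @export
partition_dataset <- function(n, k = 5L, seed = 1L) {
  if (!is.numeric(n) || length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (n < k) stop("cannot split fewer items than subsets", call. = FALSE)
  sizes <- rep(n %/% k, k)
  sizes[k] <- sizes[k] + n %% k
  assignments <- integer(n)
  with_seed(seed, {
    assignments[sample.int(n)] <- rep.int(seq_len(k), times = sizes)
  })
  structure(list(assignments = assignments, sizes = sizes, k = k),
            class = "subset_split")
}

#' Average malignancy probabilities over randomized repetitions
#'
#' @param prob_table Numeric matrix, nodules in rows, repetitions in columns.
#' @return Per-nodule mean score vector.
#' @export
repetition_average <- function(prob_table) {
  prob_table <- as.matrix(prob_table)
  if (ncol(prob_table) < 1L || anyNA(prob_table)) {
    stop("every nodule needs at least one repetition and no missing values",
         call. = FALSE)
  }
  rowMeans(prob_table)
}

#' Paired t-tests of per-subset AUCs between regions
#'
#' @param auc_table Numeric matrix, subsets in rows, regions in columns.
#' @return List with `p_values` (pairwise matrix, diagonal 1; zero-difference
#'   pairs are degenerate and reported as 1), `means` and `sds` per region
#'   (bar-plot-ready), and `degenerate` (logical matrix).
#' @export
paired_ttest_regions <- function(auc_table) {
  auc_table <- as.matrix(auc_table)
  if (nrow(auc_table) < 2L) {
    stop("paired t-tests require at least 2 subsets", call. = FALSE)
  }
  k <- ncol(auc_table)
  nm <- colnames(auc_table)
  if (is.null(nm)) nm <- as.character(utils::as.roman(seq_len(k)))
  p <- matrix(1, k, k, dimnames = list(nm, nm))
  deg <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      d <- auc_table[, i] - auc_table[, j]
      if (stats::sd(d) < .Machine$double.eps^0.5) {
        deg[i, j] <- deg[j, i] <- TRUE
        p[i, j] <- p[j, i] <- if (all(abs(d) < .Machine$double.eps^0.5)) 1 else 0
      } else {
        p[i, j] <- p[j, i] <- stats::t.test(auc_table[, i], auc_table[, j],
                                            paired = TRUE)$p.value
      }
    }
  }
  list(p_values = p, means = colMeans(auc_table),
       sds = apply(auc_table, 2, stats::sd), degenerate = deg)
}

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty masks are defined to agree
#' perfectly (Dice 1).
#'
#' @param mask_a,mask_b Logical (or 0/1) matrices of identical dimensions.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) {
    stop("masks must have identical dimensions", call. = FALSE)
  }
  a <- as.logical(mask_a)
  b <- as.logical(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
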