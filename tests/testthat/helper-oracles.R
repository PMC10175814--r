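# Independent oracles (explicit loops / brute force) against which the
# vectorized implementations are checked, plus small shared fixtures.

# AUC by exhaustive pairwise concordance (ties get half credit).
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (x in pos) {
    for (y in neg) {
      total <- total + if (x > y) 1 else if (x == y) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# DeLong's test recomputed with explicit loops over the placement-value
# (structural-component) covariance formulas.
oracle_delong <- function(labels, scores_a, scores_b) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  m <- length(pos)
  n <- length(neg)
  psi <- function(x, y) if (x > y) 1 else if (x == y) 0.5 else 0
  comp <- function(scores) {
    v10 <- numeric(m)
    v01 <- numeric(n)
    for (i in seq_len(m)) {
      for (j in seq_len(n)) {
        p <- psi(scores[pos[i]], scores[neg[j]])
        v10[i] <- v10[i] + p / n
        v01[j] <- v01[j] + p / m
      }
    }
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  a <- comp(scores_a)
  b <- comp(scores_b)
  covl <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    s <- 0
    for (i in seq_along(x)) s <- s + (x[i] - mx) * (y[i] - my)
    s / (length(x) - 1)
  }
  var_d <- (covl(a$v10, a$v10) + covl(b$v10, b$v10) - 2 * covl(a$v10, b$v10)) / m +
    (covl(a$v01, a$v01) + covl(b$v01, b$v01) - 2 * covl(a$v01, b$v01)) / n
  if (var_d <= 0) return(1)
  2 * stats::pnorm(-abs((a$auc - b$auc) / sqrt(var_d)))
}

# Equal-area partition oracle: sort positive pixels by (value, linear index)
# and split into k consecutive blocks, remainder to the innermost regions.
oracle_sort_split <- function(cam, k) {
  v <- as.vector(cam)
  pos <- which(v > 0)
  o <- pos[order(v[pos], pos)]
  N <- length(o)
  base <- N %/% k
  sizes <- rep(base, k)
  rem <- N %% k
  if (rem > 0) sizes[(k - rem + 1):k] <- base + 1
  lab <- integer(length(v))
  start <- 1
  for (j in seq_len(k)) {
    lab[o[start:(start + sizes[j] - 1)]] <- j
    start <- start + sizes[j]
  }
  matrix(lab, nrow(cam), ncol(cam))
}

# CAM by explicit triple loop over grid positions and feature maps.
oracle_cam <- function(feature_stack, weights) {
  d <- dim(feature_stack)
  out <- matrix(0, d[1], d[2])
  for (x in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        out[x, y] <- out[x, y] + weights[k] * feature_stack[x, y, k]
      }
    }
  }
  out
}

# Connected components of a logical mask (4-neighbourhood flood fill).
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      r <- (p - 1L) %% nrow(mask) + 1L
      cc <- (p - 1L) %/% nrow(mask) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc2 <- cc + d[2]
        if (rr >= 1 && rr <= nrow(mask) && cc2 >= 1 && cc2 <= ncol(mask)) {
          q <- (cc2 - 1L) * nrow(mask) + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- comp
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  comp
}

# A fabricated classifier output for heatmap tests that bypasses the network.
fake_output <- function(feature_stack, head_weights) {
  K <- dim(feature_stack)[3]
  stopifnot(nrow(head_weights) == K)
  pooled <- vapply(seq_len(K), function(k) sum(feature_stack[, , k]),
                   numeric(1))
  s <- as.vector(pooled %*% head_weights)
  p <- exp(s - max(s)); p <- p / sum(p)
  structure(list(feature_stack = feature_stack, pooled = pooled,
                 class_scores = s, probabilities = p,
                 predicted_class = which.max(p), head_weights = head_weights),
            class = "classifier_output")
}

# Small, fast phantom configuration for unit tests (full-size defaults are
# exercised by the acceptance suite).
tiny_phantom <- function(...) {
  phantom_config(image_size = 48L, nodule_area_range = c(180L, 320L),
                 calcification_count_range = c(1L, 3L), ...)
}

tiny_spec <- function(input_size = 48L) {
  model_spec(input_size = input_size, channels = c(4L, 8L),
             kernel_sizes = c(5L, 3L), strides = c(2L, 2L))
}
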