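# Fast gradient sign method noise, region-restricted application with
# randomized positions, and the AUC-gradient rule for choosing the noise
# magnitude beta.

#' Perturbation specification
#'
#' @param beta Max-norm noise magnitude (>= 0): the maximum change to any
#'   pixel value.
#' @param region_label Target region index (1..k) or `"all"` for the full
#'   nodular support.
#' @param position_fraction Fraction of the region's pixels perturbed per
#'   repetition, in (0, 1]. Randomizing the perturbed positions across
#'   repetitions is what makes repetition averaging meaningful.
#' @param n_repetitions Number of randomized repetitions (default 5).
#' @param seed Base seed; repetition r draws its positions from
#'   `seed * r`.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(beta, region_label = "all",
                              position_fraction = 0.8,
                              n_repetitions = 5L, seed = 1L) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  stopifnot(n_repetitions >= 1, position_fraction > 0, position_fraction <= 1)
  structure(list(beta = beta, region_label = region_label,
                 position_fraction = position_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' FGSM noise field
#'
#' `delta = beta * sign(gradient)` elementwise, with `sign(0) = 0`.
#'
#' @param gradient Loss gradient raster from [input_gradient()].
#' @param beta Max-norm magnitude (>= 0).
#' @return Object of class `noise_field`: `delta` raster and `support`
#'   (logical, where the noise may act; full support here).
#' @export
fgsm_noise <- function(gradient, beta) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  stopifnot(is.matrix(gradient), all(is.finite(gradient)))
  structure(list(delta = beta * sign(gradient),
                 support = matrix(TRUE, nrow(gradient), ncol(gradient))),
            class = "noise_field")
}

# Deterministic per-repetition seed; kept inside 32-bit integer range.
repetition_seed <- function(seed, repetition_index) {
  as.integer((as.double(seed) * as.double(repetition_index)) %% 2147483647)
}

#' Apply noise to a random subset of a region
#'
#' A uniformly random subset of `ceiling(position_fraction * |region|)`
#' region pixels (seeded by `spec$seed * repetition_index`) receives the
#' noise; every other pixel is bit-identical to the input. The result is
#' clipped to `[0, 1]`, so `max |x' - x| <= beta` always.
#'
#' @param image Image matrix in `[0, 1]`.
#' @param noise A [fgsm_noise()] field aligned with `image`.
#' @param region_mask Logical matrix selecting the target region.
#' @param spec A [perturbation_spec()].
#' @param repetition_index Which repetition (1..n_repetitions).
#' @return The perturbed image `x'`.
#' @export
apply_regional <- function(image, noise, region_mask, spec,
                           repetition_index = 1L) {
  stopifnot(inherits(noise, "noise_field"),
            all(dim(image) == dim(noise$delta)),
            all(dim(image) == dim(region_mask)))
  px <- which(region_mask & noise$support)
  if (length(px) == 0L) {
    warning("empty region mask: image returned unchanged")
    return(image)
  }
  n_pick <- ceiling(spec$position_fraction * length(px))
  sel <- with_seed(repetition_seed(spec$seed, repetition_index), {
    if (n_pick >= length(px)) px else px[sample.int(length(px), n_pick)]
  })
  out <- image
  out[sel] <- out[sel] + noise$delta[sel]
  pmin(pmax(out, 0), 1)
}

#' Select the noise magnitude by the AUC-gradient rule
#'
#' Perturbs the full nodular support of every image at each grid magnitude,
#' recomputes the dataset AUC, takes finite differences of AUC with respect
#' to beta (central in the interior, one-sided at the ends) and returns the
#' grid point where `|dAUC/dbeta|` is largest — the magnitude at which the
#' classifier's performance decays fastest.
#'
#' @param model A trained `gapnet` model.
#' @param dataset A `nodule_dataset`.
#' @param beta_grid Ascending magnitudes, at least 3 points (typically
#'   starting at 0 as the clean control).
#' @param gradients Optional precomputed list of loss gradients (one per
#'   nodule) to avoid recomputation.
#' @return List with `beta` (the selected magnitude), `table` (data frame of
#'   beta, auc, dauc) and `clean_auc` (AUC at the smallest grid point).
#' @export
select_beta <- function(model, dataset, beta_grid, gradients = NULL) {
  stopifnot(length(beta_grid) >= 3, !is.unsorted(beta_grid))
  labels <- dataset_label_int(dataset)
  if (is.null(gradients)) {
    gradients <- input_gradients(model, dataset)
  }
  signs <- lapply(gradients, sign)
  aucs <- vapply(beta_grid, function(beta) {
    imgs <- lapply(seq_along(dataset), function(i) {
      x <- dataset[[i]]$image
      d <- beta * signs[[i]]
      d[!dataset[[i]]$nodule_mask] <- 0
      pmin(pmax(x + d, 0), 1)
    })
    roc_auc(labels, gapnet_predict(model, imgs)[, 2])$auc
  }, numeric(1))
  res <- beta_gradient_select(beta_grid, aucs)
  c(res, list(clean_auc = aucs[1]))
}

# Finite-difference |dAUC/dbeta| maximizer: central differences in the
# interior, one-sided at the ends. A zero grid point (the clean control) is
# kept in the table but is not selectable — a null magnitude is not a
# perturbation size, and for a classifier whose AUC decays fastest right at
# the origin the argmax would otherwise degenerate to "no noise".
beta_gradient_select <- function(beta_grid, aucs) {
  if (max(aucs) - min(aucs) < 1e-12) {
    stop("AUC is constant across the beta grid; widen the grid", call. = FALSE)
  }
  g <- length(beta_grid)
  dauc <- numeric(g)
  dauc[1] <- (aucs[2] - aucs[1]) / (beta_grid[2] - beta_grid[1])
  dauc[g] <- (aucs[g] - aucs[g - 1]) / (beta_grid[g] - beta_grid[g - 1])
  if (g > 2) {
    for (i in 2:(g - 1)) {
      dauc[i] <- (aucs[i + 1] - aucs[i - 1]) / (beta_grid[i + 1] - beta_grid[i - 1])
    }
  }
  selectable <- which(beta_grid > 0)
  sel <- selectable[which.max(abs(dauc[selectable]))]
  list(beta = beta_grid[sel],
       table = data.frame(beta = beta_grid, auc = aucs, dauc = dauc))
}
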