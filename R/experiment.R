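# End-to-end experiment orchestration: train the stand-in classifier on the
# phantom, derive per-nodule CAM partitions, perturb each region with FGSM
# noise at the calibrated magnitude, and run the statistical protocol
# (repetition-averaged per-region ROC/AUC, DeLong matrix, subset split with
# paired t-tests).

#' Experiment configuration
#'
#' Bundles every stage's settings; the global `seed` propagates
#' deterministically to the phantom, the training split, the subset split
#' and the randomized perturbation positions.
#'
#' @param phantom A [phantom_config()].
#' @param n_benign,n_malignant Dataset class counts.
#' @param train A [train_config()].
#' @param beta_grid Ascending FGSM magnitudes for [select_beta()]; the first
#'   point should be 0 (clean control).
#' @param position_fraction Fraction of region pixels perturbed per
#'   repetition.
#' @param n_repetitions Randomized position repetitions per region.
#' @param k_regions Number of equal-area CAM regions.
#' @param k_subsets Number of random subsets for the paired t-test stage.
#' @param malignancy_cohort_threshold Minimum clean predicted malignancy
#'   probability for inclusion in the malignancy-heat-map experiment cohort.
#' @param out_dir Optional output directory for artifacts (CSV tables,
#'   provenance JSON, rendered PNGs).
#' @param seed Global seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_config(),
                              n_benign = 200L, n_malignant = 200L,
                              train = train_config(epochs = 15L,
                                                   early_stop_auc = 0.99),
                              beta_grid = c(0, 0.002, 0.005, 0.01, 0.02, 0.04),
                              position_fraction = 0.8,
                              n_repetitions = 5L,
                              k_regions = 5L,
                              k_subsets = 5L,
                              malignancy_cohort_threshold = 0.4,
                              out_dir = NULL,
                              seed = 1L) {
  stopifnot(inherits(phantom, "phantom_config"), inherits(train, "train_config"))
  # the global seed wins: it propagates to every stage
  phantom$seed <- as.integer(seed)
  train$seed <- as.integer(seed)
  structure(list(phantom = phantom, n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant), train = train,
                 beta_grid = beta_grid,
                 position_fraction = position_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 k_regions = as.integer(k_regions),
                 k_subsets = as.integer(k_subsets),
                 malignancy_cohort_threshold = malignancy_cohort_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

# Rebuild an experiment_config from a plain (e.g. YAML) list, keeping
# defaults for absent keys.
as_experiment_config <- function(x) {
  if (inherits(x, "experiment_config")) return(x)
  stopifnot(is.list(x))
  ph <- do.call(phantom_config, as.list(x$phantom))
  tr <- do.call(train_config, as.list(x$train))
  args <- x[setdiff(names(x), c("phantom", "train"))]
  do.call(experiment_config, c(list(phantom = ph, train = tr), args))
}

#' Read / write an experiment config as YAML
#'
#' @param path YAML file path.
#' @return `read_experiment_config` returns an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  as_experiment_config(yaml::read_yaml(path))
}

#' @rdname read_experiment_config
#' @param config An `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$phantom <- unclass(x$phantom)
  x$train <- unclass(x$train)
  x$train$early_stop_auc <- x$train$early_stop_auc %||% NA
  yaml::write_yaml(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate and write a phantom dataset
#'
#' @param config An [experiment_config()].
#' @return Invisibly, the manifest data frame (written to
#'   `out_dir/dataset/manifest.csv` when `out_dir` is set).
#' @export
run_simulate <- function(config) {
  config <- as_experiment_config(config)
  ds <- generate_dataset(config$phantom, config$n_benign, config$n_malignant,
                         seed = config$seed)
  if (!is.null(config$out_dir)) {
    manifest <- write_dataset(ds, file.path(config$out_dir, "dataset"))
    write_provenance(config, file.path(config$out_dir, "dataset"))
    invisible(manifest)
  } else {
    invisible(write_dataset_manifest(ds))
  }
}

write_dataset_manifest <- function(ds) {
  data.frame(id = sprintf("nodule_%04d", seq_along(ds)),
             label = dataset_labels(ds),
             n_pixels = vapply(ds, function(s) s$feature_record$n_pixels,
                               numeric(1)))
}

# Upsampled raw (signed) malignant/predicted-class CAM for each nodule, plus
# clean probabilities. map = "predicted" uses each nodule's predicted-class
# CAM (conventional rendering); map = "malignant" always uses the
# malignant-class CAM (malignancy heat map variant).
dataset_cams <- function(model, dataset, map = c("malignant", "predicted"),
                         chunk = 32L) {
  map <- match.arg(map)
  n <- length(dataset)
  H <- model$spec$input_size
  p_clean <- matrix(NA_real_, n, model$spec$classes)
  ups <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    x <- as_image_batch(dataset[i:j], H)
    fwd <- gapnet_forward_batch(model, x)
    p_clean[i:j, ] <- fwd$P
    dims <- dim(fwd$feat)
    flat <- matrix(fwd$feat, dims[1] * dims[2] * dims[3], dims[4])
    for (b in seq_len(j - i + 1L)) {
      feat_b <- matrix(flat[, b], dims[1] * dims[2], dims[3])
      ci <- if (map == "malignant") 2L else which.max(fwd$P[b, ])
      cam <- matrix(feat_b %*% model$head[, ci], dims[1], dims[2])
      ups[[i + b - 1L]] <- bilinear_resize(cam, H, H)
    }
    i <- j + 1L
  }
  list(p_clean = p_clean, upsampled = ups)
}

# Seeded class-stratified partition into k subsets: each class is split by
# cycling a shuffled order over the subsets, so subset sizes differ by at
# most one per class and every subset carries both classes whenever each
# class has at least k members.
stratified_subsets <- function(labels, k, seed) {
  assignments <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- if (length(idx) > 1L) sample(idx) else idx
      assignments[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  sizes <- tabulate(assignments, nbins = k)
  structure(list(assignments = assignments, sizes = sizes, k = k),
            class = "subset_split")
}

# Equal-area partition of a nodular CAM: clamp the upsampled map, restrict to
# the nodule mask; if clamping leaves fewer than k positive pixels (a map
# that is negative over the nodule), fall back to a rank-preserving shift
# inside the mask so the partition is still defined.
partition_for_nodule <- function(up_raw, mask, k) {
  v <- pmax(up_raw, 0)
  v[!mask] <- 0
  if (sum(v > 0) < k) {
    v <- up_raw - min(up_raw[mask]) + 1e-9
    v[!mask] <- 0
  }
  segment_equal_areas(v, k)
}

# Shared engine for both experiments. Returns per-region repetition-averaged
# scores, ROC/AUC, the DeLong matrix, and the subset-level AUC table with
# paired t-tests.
run_region_perturbation <- function(model, dataset, config,
                                    map = c("predicted", "malignant"),
                                    cohort = seq_along(dataset)) {
  map <- match.arg(map)
  labels <- dataset_label_int(dataset)[cohort]
  if (length(unique(labels)) < 2L) {
    stop("perturbation cohort contains a single class; lower the cohort threshold",
         call. = FALSE)
  }
  ds <- dataset[cohort]
  cams <- dataset_cams(model, ds, map = map)
  p_clean <- cams$p_clean[, 2]
  partitions <- lapply(seq_along(ds), function(i) {
    partition_for_nodule(cams$upsampled[[i]], ds[[i]]$nodule_mask,
                         config$k_regions)
  })
  grads <- input_gradients(model, ds)
  sel <- select_beta(model, ds, config$beta_grid, gradients = grads)
  beta <- sel$beta
  noises <- lapply(grads, fgsm_noise, beta = beta)
  n <- length(ds)
  k <- config$k_regions
  reps <- config$n_repetitions
  probs <- array(NA_real_, c(n, k, reps))
  for (r in seq_len(k)) {
    for (t in seq_len(reps)) {
      imgs <- lapply(seq_len(n), function(i) {
        spec_i <- perturbation_spec(
          beta, region_label = r,
          position_fraction = config$position_fraction,
          n_repetitions = reps,
          seed = (config$seed * 131071 + i * 7919) %% 2147483647)
        apply_regional(ds[[i]]$image, noises[[i]],
                       region_mask(partitions[[i]], r), spec_i,
                       repetition_index = t)
      })
      probs[, r, t] <- gapnet_predict(model, imgs)[, 2]
    }
  }
  region_names <- as.character(utils::as.roman(seq_len(k)))
  region_scores <- sapply(seq_len(k), function(r) {
    repetition_average(probs[, r, , drop = TRUE])
  })
  colnames(region_scores) <- region_names
  rocs <- lapply(seq_len(k), function(r) roc_auc(labels, region_scores[, r]))
  names(rocs) <- region_names
  aucs <- vapply(rocs, function(x) x$auc, numeric(1))
  pmat <- pvalue_matrix(rocs)
  clean_roc <- roc_auc(labels, p_clean)

  # class-stratified subsets: a plain random split can leave a subset
  # single-class (undefined AUC) when one class is rare in the cohort
  split <- stratified_subsets(labels, k = config$k_subsets,
                              seed = config$seed + 11L)
  auc_table <- matrix(NA_real_, config$k_subsets, k,
                      dimnames = list(NULL, region_names))
  for (s in seq_len(config$k_subsets)) {
    idx <- which(split$assignments == s)
    if (length(unique(labels[idx])) < 2L) next
    for (r in seq_len(k)) {
      auc_table[s, r] <- roc_auc(labels[idx], region_scores[idx, r])$auc
    }
  }
  complete <- stats::complete.cases(auc_table)
  ttests <- if (sum(complete) >= 2L) {
    paired_ttest_regions(auc_table[complete, , drop = FALSE])
  } else {
    warning("too few two-class subsets for paired t-tests")
    NULL
  }

  list(map = map, cohort = cohort, labels = labels,
       p_clean = p_clean, clean_auc = clean_roc$auc, clean_roc = clean_roc,
       beta = beta, beta_table = sel$table,
       region_scores = region_scores, rocs = rocs, aucs = aucs,
       pvalue_matrix = pmat, subset_split = split, auc_table = auc_table,
       ttests = ttests, partitions = partitions)
}

#' Regional-importance experiment on the conventional CAM
#'
#' Trains the stand-in classifier on a fresh phantom dataset, partitions each
#' nodule's predicted-class CAM into equal-area nested regions, perturbs each
#' region with FGSM noise at the AUC-gradient-selected magnitude (positions
#' randomized over `n_repetitions` repetitions, probabilities averaged), and
#' computes per-region ROC/AUC, the pairwise DeLong matrix, and the
#' subset-split paired t-tests.
#'
#' @param config An [experiment_config()].
#' @return Object of class `region_experiment` (see
#'   [run_region_perturbation] internals): per-region AUCs, p-value matrices,
#'   subset AUC table, the selected beta and its AUC table, and the trained
#'   model under `$model`.
#' @export
run_experiment_regions <- function(config) {
  config <- as_experiment_config(config)
  ds <- generate_dataset(config$phantom, config$n_benign, config$n_malignant,
                         seed = config$seed)
  fit <- gapnet_train(model_spec(input_size = config$phantom$image_size),
                      ds, config$train)
  bundle <- run_region_perturbation(fit$model, ds, config, map = "predicted")
  bundle$model <- fit$model
  bundle$train_metrics <- fit$metrics
  bundle$val_idx <- fit$val_idx
  bundle$config <- config
  class(bundle) <- "region_experiment"
  if (!is.null(config$out_dir)) write_experiment_artifacts(bundle, config)
  bundle
}

#' Regional-importance experiment on the malignancy heat map
#'
#' As [run_experiment_regions()], but regions are derived from the
#' malignancy heat map (malignant-class CAM scaled by the predicted
#' malignancy probability) and the analysis is restricted to the cohort of
#' nodules with clean predicted malignancy probability above
#' `malignancy_cohort_threshold`.
#'
#' @param config An [experiment_config()].
#' @return A `region_experiment` bundle (with `$cohort` the retained indices).
#' @export
run_experiment_malignancy <- function(config) {
  config <- as_experiment_config(config)
  ds <- generate_dataset(config$phantom, config$n_benign, config$n_malignant,
                         seed = config$seed)
  fit <- gapnet_train(model_spec(input_size = config$phantom$image_size),
                      ds, config$train)
  p_clean <- gapnet_predict(fit$model, ds)[, 2]
  cohort <- which(p_clean > config$malignancy_cohort_threshold)
  if (length(cohort) == 0L) {
    stop("empty malignancy cohort; lower malignancy_cohort_threshold",
         call. = FALSE)
  }
  bundle <- run_region_perturbation(fit$model, ds, config, map = "malignant",
                                    cohort = cohort)
  bundle$model <- fit$model
  bundle$train_metrics <- fit$metrics
  bundle$val_idx <- fit$val_idx
  bundle$config <- config
  class(bundle) <- "region_experiment"
  if (!is.null(config$out_dir)) write_experiment_artifacts(bundle, config)
  bundle
}

#' @export
print.region_experiment <- function(x, ...) {
  cat(sprintf("<region_experiment> map = %s, %d nodules, beta = %g\n",
              x$map, length(x$labels), x$beta))
  cat(sprintf("  clean AUC %.4f; per-region AUC: %s\n", x$clean_auc,
              paste(sprintf("%s=%.4f", names(x$aucs), x$aucs), collapse = " ")))
  invisible(x)
}

#' Heat-intensity threshold sweep
#'
#' For each relative threshold, keeps the nodular pixels whose CAM value
#' reaches that fraction of the per-nodule maximum and replaces the
#' sub-threshold nodular remainder with the image's own parenchyma level
#' (the median intensity outside the nodule), then recomputes the dataset
#' AUC. The image outside the nodule is untouched, so the threshold-0 sweep
#' point is the clean image and rising thresholds progressively erase
#' nodular evidence.
#'
#' @param model A trained `gapnet`.
#' @param dataset A `nodule_dataset`.
#' @param rel_thresholds Ascending relative heat cuts in `[0, 1)`.
#' @return Data frame with `threshold`, `auc` and the mean retained nodular
#'   area.
#' @export
run_threshold_sweep <- function(model, dataset,
                                rel_thresholds = seq(0, 0.8, by = 0.2)) {
  stopifnot(!is.unsorted(rel_thresholds))
  labels <- dataset_label_int(dataset)
  cams <- dataset_cams(model, dataset, map = "malignant")
  nodular <- lapply(seq_along(dataset), function(i) {
    v <- pmax(cams$upsampled[[i]], 0)
    v[!dataset[[i]]$nodule_mask] <- 0
    if (max(v) == 0) {
      v <- cams$upsampled[[i]] - min(cams$upsampled[[i]][dataset[[i]]$nodule_mask]) + 1e-9
      v[!dataset[[i]]$nodule_mask] <- 0
    }
    v
  })
  fill <- vapply(seq_along(dataset), function(i) {
    stats::median(dataset[[i]]$image[!dataset[[i]]$nodule_mask])
  }, numeric(1))
  res <- lapply(rel_thresholds, function(rt) {
    areas <- numeric(length(dataset))
    imgs <- lapply(seq_along(dataset), function(i) {
      v <- nodular[[i]]
      keep <- threshold_sweep(v, rt * max(v))[[1]]
      areas[i] <<- sum(keep)
      img <- dataset[[i]]$image
      img[dataset[[i]]$nodule_mask & !keep] <- fill[i]
      img
    })
    auc <- roc_auc(labels, gapnet_predict(model, imgs)[, 2])$auc
    data.frame(threshold = rt, auc = auc, mean_area = mean(areas))
  })
  do.call(rbind, res)
}

#' Dice evaluation of CAM-derived nodule localization
#'
#' Binarizes each nodule's clamped malignancy CAM at a fraction of its
#' maximum and compares the resulting mask to the ground-truth nodule mask.
#'
#' @param model A trained `gapnet`.
#' @param dataset A `nodule_dataset`.
#' @param rel_threshold Relative heat cut defining the derived mask.
#' @return Data frame of per-nodule Dice coefficients with attribute
#'   `median_dice`.
#' @export
run_dice_eval <- function(model, dataset, rel_threshold = 0.2) {
  cams <- dataset_cams(model, dataset, map = "malignant")
  d <- vapply(seq_along(dataset), function(i) {
    v <- pmax(cams$upsampled[[i]], 0)
    derived <- v >= rel_threshold * max(max(v), 1e-12)
    dice(derived, dataset[[i]]$nodule_mask)
  }, numeric(1))
  out <- data.frame(nodule = seq_along(dataset),
                    label = dataset_labels(dataset), dice = d)
  attr(out, "median_dice") <- stats::median(d)
  out
}

#' TI-RADS report from a ratings CSV
#'
#' @param ratings_csv CSV with one row per nodule and region class (see
#'   [tabulate_from_ratings()]).
#' @param out_csv Optional output path for the scored table.
#' @return Data frame mirroring the reader-study layout: per region class the
#'   category counts, probabilities and weighted scores, plus the summed
#'   scores.
#' @export
run_report_tirads <- function(ratings_csv, out_csv = NULL) {
  ratings <- utils::read.csv(ratings_csv, stringsAsFactors = FALSE)
  tables <- tabulate_from_ratings(ratings)
  rows <- lapply(names(tables), function(rc) {
    sc <- weighted_scores(tables[[rc]])
    df <- sc$per_category
    df$region_class <- rc
    df$total <- sc$total
    df
  })
  report <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(report, out_csv, row.names = FALSE)
  report
}

write_provenance <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  x <- unclass(config)
  x$phantom <- unclass(x$phantom)
  x$train <- unclass(x$train)
  jsonlite::write_json(
    list(config = x,
         package = as.character(utils::packageVersion("camsens")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

write_experiment_artifacts <- function(bundle, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(region = names(bundle$aucs), auc = bundle$aucs),
                   file.path(dir, "region_aucs.csv"), row.names = FALSE)
  utils::write.csv(bundle$beta_table, file.path(dir, "beta_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$pvalue_matrix$p_values),
                   file.path(dir, "delong_pvalues.csv"))
  utils::write.csv(as.data.frame(bundle$auc_table),
                   file.path(dir, "subset_aucs.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$ttests$p_values),
                   file.path(dir, "ttest_pvalues.csv"))
  for (r in names(bundle$rocs)) {
    utils::write.csv(bundle$rocs[[r]]$curve,
                     file.path(dir, sprintf("roc_region_%s.csv", r)),
                     row.names = FALSE)
  }
  write_provenance(config, dir)
  try_write_figures(bundle, dir)
  invisible(dir)
}

# Rendered figure replicas (per-region AUC bars, ROC curves, p-value tiles).
# Rendering needs a PNG graphics device; silently skipped if unavailable.
try_write_figures <- function(bundle, dir) {
  ok <- tryCatch(isTRUE(capabilities("png")), error = function(e) FALSE)
  if (!ok) return(invisible(FALSE))
  tryCatch({
    grDevices::png(file.path(dir, "region_auc_bars.png"), 720, 520)
    mids <- graphics::barplot(bundle$ttests$means,
                              ylim = c(0, 1.05),
                              ylab = "AUC (mean over subsets)",
                              xlab = "perturbed region",
                              col = "steelblue")
    graphics::arrows(mids, bundle$ttests$means - bundle$ttests$sds,
                     mids, bundle$ttests$means + bundle$ttests$sds,
                     angle = 90, code = 3, length = 0.05)
    grDevices::dev.off()

    grDevices::png(file.path(dir, "roc_curves.png"), 640, 640)
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "FPR",
                   ylab = "TPR", main = "Per-region perturbed ROC")
    cols <- grDevices::hcl.colors(length(bundle$rocs), "Zissou 1")
    for (i in seq_along(bundle$rocs)) {
      graphics::lines(bundle$rocs[[i]]$curve$fpr, bundle$rocs[[i]]$curve$tpr,
                      col = cols[i], lwd = 2)
    }
    graphics::abline(0, 1, lty = 3)
    graphics::legend("bottomright",
                     sprintf("%s (AUC %.3f)", names(bundle$aucs), bundle$aucs),
                     col = cols, lwd = 2, bty = "n")
    grDevices::dev.off()

    grDevices::png(file.path(dir, "pvalue_matrix.png"), 560, 560)
    pm <- bundle$pvalue_matrix$display
    graphics::image(seq_len(nrow(pm)), seq_len(ncol(pm)),
                    log10(pm)[, rev(seq_len(ncol(pm)))],
                    axes = FALSE, xlab = "", ylab = "",
                    main = "log10 DeLong p-values")
    graphics::axis(1, seq_len(nrow(pm)), rownames(pm))
    graphics::axis(2, seq_len(ncol(pm)), rev(colnames(pm)))
    grDevices::dev.off()
    invisible(TRUE)
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    invisible(FALSE)
  })
}
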