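# Synthetic B-mode nodule phantom.
#
# The phantom stands in for clinical ultrasound data: each image is an
# elliptical nodule embedded in multiplicative speckle, with the class signal
# carried by localized sub-nodular cues (a very hypoechoic core, punctate
# echogenic foci, margin irregularity) so that regional-importance analyses
# have a known ground truth.

#' Phantom generator configuration
#'
#' Defines the stated world of the synthetic nodule generator. Echogenicity
#' values are mean envelope intensities in `[0, 1]`; per-nodule levels are
#' drawn around these class means (`echogenicity_sd`) so that overall
#' brightness alone does not perfectly separate the classes and the
#' discriminative burden falls on the localized cues.
#'
#' @param image_size Side length in pixels of the square image.
#' @param nodule_area_range Length-2 integer vector, admissible nodule area
#'   (pixel count) interval.
#' @param benign_echogenicity Mean envelope intensity of benign nodules.
#' @param malignant_echogenicity Mean envelope intensity of malignant nodules
#'   (hypoechoic, i.e. darker than benign).
#' @param calcification_count_range Length-2 integer vector, number of
#'   punctate echogenic foci rendered in malignant nodules.
#' @param margin_irregularity Amplitude (>= 0) of the sinusoidal radial
#'   perturbation of the malignant nodule boundary; benign margins are smooth.
#' @param speckle_scale Standard deviation of the unit-mean multiplicative
#'   speckle field (0 disables speckle).
#' @param cue_localization Placement of the class-discriminative cue region:
#'   `"center"`, `"annulus"` or `"random"`.
#' @param echogenicity_sd Per-nodule standard deviation around the class mean
#'   echogenicity.
#' @param background_level Envelope intensity of the surrounding parenchyma.
#' @param macro_calcification_prob Probability that a malignant nodule carries
#'   a macro-calcification (>= 4 px focus) instead of purely punctate foci.
#' @param seed Default seed used when none is passed to the generators.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L,
                           nodule_area_range = c(900L, 2200L),
                           benign_echogenicity = 0.52,
                           malignant_echogenicity = 0.42,
                           calcification_count_range = c(2L, 5L),
                           margin_irregularity = 0.15,
                           speckle_scale = 0.35,
                           cue_localization = c("center", "annulus", "random"),
                           echogenicity_sd = 0.08,
                           background_level = 0.45,
                           macro_calcification_prob = 0,
                           seed = 1L) {
  cue_localization <- match.arg(cue_localization)
  cfg <- list(
    image_size = as.integer(image_size),
    nodule_area_range = as.integer(nodule_area_range),
    benign_echogenicity = benign_echogenicity,
    malignant_echogenicity = malignant_echogenicity,
    calcification_count_range = as.integer(calcification_count_range),
    margin_irregularity = margin_irregularity,
    speckle_scale = speckle_scale,
    cue_localization = cue_localization,
    echogenicity_sd = echogenicity_sd,
    background_level = background_level,
    macro_calcification_prob = macro_calcification_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  if (cfg$image_size < 16L) {
    stop("image_size must be at least 16 pixels", call. = FALSE)
  }
  levels <- c(cfg$benign_echogenicity, cfg$malignant_echogenicity,
              cfg$background_level)
  if (any(levels < 0 | levels > 1)) {
    stop("all echogenicity levels must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$nodule_area_range) != 2L ||
      any(cfg$nodule_area_range <= 0) ||
      cfg$nodule_area_range[1] > cfg$nodule_area_range[2]) {
    stop("nodule_area_range must be a non-decreasing positive interval",
         call. = FALSE)
  }
  # the nodule must fit inside the image with a safety margin for the
  # irregular boundary
  max_radius <- sqrt(cfg$nodule_area_range[2] / pi) * (1 + cfg$margin_irregularity)
  if (max_radius > cfg$image_size / 2 - 2) {
    stop("nodule_area_range is infeasible for image_size", call. = FALSE)
  }
  if (cfg$speckle_scale < 0 || cfg$margin_irregularity < 0) {
    stop("speckle_scale and margin_irregularity must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

# Evaluate a star-shaped nodule mask from a radial boundary function.
# radius_fun maps polar angle (vector) to boundary radius.
radial_mask <- function(image_size, center, radius_fun) {
  xs <- seq_len(image_size)
  gx <- matrix(xs, image_size, image_size, byrow = TRUE) - center[1]
  gy <- matrix(xs, image_size, image_size) - center[2]
  r <- sqrt(gx^2 + gy^2)
  theta <- atan2(gy, gx)
  r <= radius_fun(theta)
}

# Disc mask helper used for cue placement and macro-calcifications.
disc_mask <- function(image_size, center, radius) {
  radial_mask(image_size, center, function(theta) rep(radius, length(theta)))
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

#' Generate one synthetic nodule image
#'
#' Renders a star-shaped elliptical nodule into a speckled background.
#' Malignant nodules carry a very hypoechoic cue region at the configured
#' localization plus punctate bright foci, and an irregular margin; benign
#' nodules are smooth, brighter ellipses. The image is the envelope times a
#' unit-mean gamma speckle field, clipped to `[0, 1]`.
#'
#' @param config A [phantom_config()].
#' @param label `"benign"` or `"malignant"`.
#' @param seed Integer seed; identical `config` + `seed` reproduce the image
#'   bit for bit.
#' @return An object of class `synthetic_nodule`: list with `image`
#'   (matrix in `[0,1]`), `nodule_mask`, `cue_mask` (logical matrices),
#'   `label`, and `feature_record` (echogenicity class, composition, foci,
#'   pixel counts).
#' @export
generate_nodule <- function(config, label = c("benign", "malignant"),
                            seed = config$seed) {
  validate_phantom_config(config)
  label <- match.arg(label)
  with_seed(seed, {
    n <- config$image_size

    # geometry: axis-aligned ellipse, area drawn from the admissible range
    area <- stats::runif(1, config$nodule_area_range[1],
                         config$nodule_area_range[2])
    aspect <- stats::runif(1, 0.65, 0.95)
    a <- sqrt(area / (pi * aspect))      # semi-axis along x
    b <- a * aspect                      # semi-axis along y
    jitter <- n * 0.06
    center <- n / 2 + stats::runif(2, -jitter, jitter)

    irregularity <- if (label == "malignant") config$margin_irregularity else 0
    if (irregularity > 0) {
      harmonics <- 3:6
      w <- stats::runif(length(harmonics))
      w <- w / sum(w)
      phases <- stats::runif(length(harmonics), 0, 2 * pi)
      radius_fun <- function(theta) {
        base <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
        mod <- rep(1, length(theta))
        for (j in seq_along(harmonics)) {
          mod <- mod + irregularity * w[j] * sin(harmonics[j] * theta + phases[j])
        }
        base * pmax(mod, 0.3)
      }
    } else {
      radius_fun <- function(theta) {
        a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
      }
    }
    nodule_mask <- radial_mask(n, center, radius_fun)

    # per-nodule echogenicity level around the class mean
    class_mean <- if (label == "malignant") config$malignant_echogenicity else
      config$benign_echogenicity
    level <- min(max(class_mean + stats::rnorm(1, 0, config$echogenicity_sd),
                     0.05), 0.95)

    envelope <- matrix(config$background_level, n, n)
    envelope[nodule_mask] <- level

    cue_mask <- matrix(FALSE, n, n)
    foci_mask <- matrix(FALSE, n, n)
    foci_type <- "none"

    if (label == "malignant") {
      # very hypoechoic cue region covering ~25% of the nodule area
      r_eff <- sqrt(sum(nodule_mask) / pi)
      cue_r <- r_eff * 0.5
      cue_center <- switch(config$cue_localization,
        center = center,
        annulus = center,  # handled below
        random = {
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0, r_eff * 0.45)
          center + rad * c(cos(ang), sin(ang))
        }
      )
      if (config$cue_localization == "annulus") {
        outer_d <- disc_mask(n, center, r_eff * 0.8)
        inner_d <- disc_mask(n, center, r_eff * 0.45)
        cue_mask <- outer_d & !inner_d & nodule_mask
      } else {
        cue_mask <- disc_mask(n, cue_center, cue_r) & nodule_mask
      }
      if (!any(cue_mask)) {
        # fallback: guarantee a non-empty cue at the nodule centroid
        cue_mask <- disc_mask(n, center, max(2, r_eff * 0.3)) & nodule_mask
      }
      envelope[cue_mask] <- 0.35 * level

      # punctate echogenic foci at the cue localization
      cc <- config$calcification_count_range
      n_foci <- if (cc[1] == cc[2]) cc[1] else sample(seq(cc[1], cc[2]), 1)
      macro <- stats::runif(1) < config$macro_calcification_prob
      host <- which(cue_mask)
      if (length(host) > 0 && n_foci > 0) {
        anchors <- sample(host, min(n_foci, length(host)))
        for (p in anchors) {
          cy <- (p - 1) %% n + 1
          cx <- (p - 1) %/% n + 1
          sz <- sample(1:3, 1)   # punctate: 1-3 px
          dy <- sample(c(0L, 0L, 1L, -1L), sz, replace = TRUE)
          dx <- sample(c(0L, 1L, -1L, 0L), sz, replace = TRUE)
          yy <- pmin(pmax(cy + dy, 1L), n)
          xx <- pmin(pmax(cx + dx, 1L), n)
          foci_mask[cbind(yy, xx)] <- TRUE
        }
        foci_type <- "punctate calcification"
        if (macro) {
          mc <- which(cue_mask)[1]
          cy <- (mc - 1) %% n + 1
          cx <- (mc - 1) %/% n + 1
          foci_mask <- foci_mask | (disc_mask(n, c(cx, cy), 1.6) & nodule_mask)
          foci_type <- "macro-calcification"
        }
        foci_mask <- foci_mask & nodule_mask
        cue_mask <- cue_mask | foci_mask
      }
    }

    speckle <- if (config$speckle_scale > 0) {
      shp <- 1 / config$speckle_scale^2
      matrix(stats::rgamma(n * n, shape = shp, rate = shp), n, n)
    } else {
      matrix(1, n, n)
    }
    image <- envelope * speckle
    # specular reflectors: foci stay bright regardless of speckle
    if (any(foci_mask)) {
      image[foci_mask] <- 0.9 + 0.1 * stats::runif(sum(foci_mask))
    }
    image <- pmin(pmax(image, 0), 1)

    echog_class <- if (label == "malignant") {
      if (sum(cue_mask) / sum(nodule_mask) > 0.15) "very hypoechoic" else "hypoechoic"
    } else {
      "isoechoic"
    }
    record <- list(
      label = label,
      echogenicity = echog_class,
      composition = "solid",
      foci = foci_type,
      n_pixels = sum(nodule_mask),
      n_cue_pixels = sum(cue_mask),
      echogenicity_level = level,
      seed = as.integer(seed %% 2147483647L)
    )
    structure(
      list(image = image, nodule_mask = nodule_mask, cue_mask = cue_mask,
           label = label, feature_record = record),
      class = "synthetic_nodule"
    )
  })
}

#' Generate a labelled phantom dataset
#'
#' Benign nodules come first, then malignant, each rendered with a per-nodule
#' seed derived deterministically from `seed`.
#'
#' @param config A [phantom_config()].
#' @param n_benign,n_malignant Non-negative class counts.
#' @param seed Dataset-level seed.
#' @return A list of [generate_nodule()] results with class `nodule_dataset`.
#' @export
generate_dataset <- function(config, n_benign, n_malignant,
                             seed = config$seed) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  nodules <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    seed_i <- (as.double(seed) * 10007 + i) %% 2147483647
    nodules[[i]] <- generate_nodule(config, labels[i], seed = seed_i)
  }
  structure(nodules, class = c("nodule_dataset", "list"))
}

#' @export
print.synthetic_nodule <- function(x, ...) {
  cat(sprintf("<synthetic_nodule> %s, %dx%d, nodule %d px, cue %d px, foci: %s\n",
              x$label, nrow(x$image), ncol(x$image),
              x$feature_record$n_pixels, x$feature_record$n_cue_pixels,
              x$feature_record$foci))
  invisible(x)
}

#' @export
print.nodule_dataset <- function(x, ...) {
  labs <- vapply(x, function(s) s$label, character(1))
  cat(sprintf("<nodule_dataset> %d nodules (%d benign, %d malignant)\n",
              length(x), sum(labs == "benign"), sum(labs == "malignant")))
  invisible(x)
}

dataset_labels <- function(dataset) {
  vapply(dataset, function(s) s$label, character(1))
}

dataset_label_int <- function(dataset) {
  as.integer(dataset_labels(dataset) == "malignant")
}

#' Write a phantom dataset to disk
#'
#' Images are written as 8-bit grayscale PNG, masks as 0/255 PNG, and the
#' labels plus per-nodule feature records as a CSV manifest.
#'
#' @param dataset A `nodule_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    id <- sprintf("nodule_%04d", i)
    write_gray_png(s$image, file.path(dir, paste0(id, ".png")))
    write_mask_png(s$nodule_mask, file.path(dir, paste0(id, "_mask.png")))
    write_mask_png(s$cue_mask, file.path(dir, paste0(id, "_cue.png")))
    data.frame(id = id, label = s$label,
               echogenicity = s$feature_record$echogenicity,
               composition = s$feature_record$composition,
               foci = s$feature_record$foci,
               n_pixels = s$feature_record$n_pixels,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
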