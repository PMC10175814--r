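# Class activation maps and the malignancy heat map variant.
#
# The CAM for class i is M_i(x,y) = sum_k omega_k^i g_k(x,y) on the last-conv
# grid, so with sum-pooled G^k the identity S_i = sum_{x,y} M_i(x,y) holds
# exactly. The malignancy heat map rescales the (non-negative) malignant-class
# CAM by its maximum and multiplies by the predicted malignancy probability,
# so the peak heat equals P_malignant and color temperature encodes absolute
# malignancy evidence.

#' Compute a class activation map
#'
#' @param output A `classifier_output` from [gapnet_forward()].
#' @param class_index Class of interest (1 = benign, 2 = malignant).
#' @return An object of class `activation_map` with `values` (the raw, signed
#'   M_i on the conv grid), `class_index`, `source_score` (S_i) and
#'   `upsampled` (`NULL` until [upsample_cam()] is applied).
#' @export
compute_cam <- function(output, class_index) {
  stopifnot(inherits(output, "classifier_output"))
  if (class_index < 1 || class_index > length(output$class_scores)) {
    stop("invalid class index", call. = FALSE)
  }
  feat <- output$feature_stack
  dims <- dim(feat)
  w <- output$head_weights[, class_index]
  values <- matrix(matrix(feat, dims[1] * dims[2], dims[3]) %*% w,
                   dims[1], dims[2])
  structure(list(values = values, class_index = class_index,
                 source_score = output$class_scores[class_index],
                 upsampled = NULL),
            class = "activation_map")
}

# Bilinear interpolation with half-pixel center alignment; an identity when
# source and target sizes coincide. Values stay within [min, max] of source.
bilinear_resize <- function(m, target_rows, target_cols) {
  hs <- nrow(m); ws <- ncol(m)
  if (target_rows == hs && target_cols == ws) return(m)
  src_y <- pmin(pmax((seq_len(target_rows) - 0.5) * hs / target_rows - 0.5, 0),
                hs - 1)
  src_x <- pmin(pmax((seq_len(target_cols) - 0.5) * ws / target_cols - 0.5, 0),
                ws - 1)
  y0 <- pmin(floor(src_y), hs - 2); y1 <- y0 + 1
  x0 <- pmin(floor(src_x), ws - 2); x1 <- x0 + 1
  if (hs == 1) { y0 <- y1 <- numeric(target_rows) * 0 }
  if (ws == 1) { x0 <- x1 <- numeric(target_cols) * 0 }
  wy <- src_y - y0; wx <- src_x - x0
  m00 <- m[y0 + 1, x0 + 1, drop = FALSE]
  m10 <- m[pmin(y1, hs - 1) + 1, x0 + 1, drop = FALSE]
  m01 <- m[y0 + 1, pmin(x1, ws - 1) + 1, drop = FALSE]
  m11 <- m[pmin(y1, hs - 1) + 1, pmin(x1, ws - 1) + 1, drop = FALSE]
  WY <- matrix(wy, target_rows, target_cols)
  WX <- matrix(wx, target_rows, target_cols, byrow = TRUE)
  m00 * (1 - WY) * (1 - WX) + m10 * WY * (1 - WX) +
    m01 * (1 - WY) * WX + m11 * WY * WX
}

#' Upsample a CAM to image resolution
#'
#' Bilinear interpolation; fills the `upsampled` slot.
#'
#' @param cam An `activation_map`.
#' @param target Length-2 integer vector (rows, cols), or a single side
#'   length; must be at least the conv-grid size.
#' @return The `activation_map` with `upsampled` set.
#' @export
upsample_cam <- function(cam, target) {
  stopifnot(inherits(cam, "activation_map"))
  if (length(target) == 1L) target <- c(target, target)
  if (any(target < dim(cam$values))) {
    stop("target size must be at least the CAM grid size", call. = FALSE)
  }
  cam$upsampled <- bilinear_resize(cam$values, target[1], target[2])
  cam
}

#' Malignancy heat map
#'
#' Clamps negative CAM values to zero, rescales by the per-nodule maximum
#' (a zero map stays zero) and multiplies by the predicted malignancy
#' probability, so `max(values) == p_malignant` for a non-degenerate map.
#'
#' @param cam An `activation_map` for the malignant class (uses the upsampled
#'   raster when present, otherwise the conv-grid values).
#' @param p_malignant Predicted malignancy probability in `[0, 1]`.
#' @return Object of class `malignancy_heatmap` with `values` and
#'   `p_malignant`.
#' @export
malignancy_heatmap <- function(cam, p_malignant) {
  stopifnot(inherits(cam, "activation_map"))
  if (p_malignant < 0 || p_malignant > 1) {
    stop("p_malignant must lie in [0, 1]", call. = FALSE)
  }
  raw <- if (!is.null(cam$upsampled)) cam$upsampled else cam$values
  v <- pmax(raw, 0)
  mx <- max(v)
  if (mx > 0) v <- v / mx
  structure(list(values = v * p_malignant, p_malignant = p_malignant),
            class = "malignancy_heatmap")
}

heat_values <- function(map) {
  if (inherits(map, "activation_map")) {
    if (!is.null(map$upsampled)) map$upsampled else map$values
  } else if (inherits(map, "malignancy_heatmap")) {
    map$values
  } else if (is.matrix(map)) {
    map
  } else {
    stop("unsupported heat map object", call. = FALSE)
  }
}

#' Render a heat map to RGB
#'
#' Two configurations. `"conventional"`: a single-ended warm colormap of the
#' relative (per-map max-normalized) intensity, agnostic to the predicted
#' class. `"malignancy"`: a diverging blue-to-red colormap anchored on the
#' absolute `[0, 1]` scale, so a reddish rendering means high predicted
#' malignancy and a bluish one benignity. Both colormaps are monotone in heat
#' (rank preserving). An optional grayscale image is alpha-blended underneath.
#'
#' @param map An `activation_map`, `malignancy_heatmap`, or plain matrix.
#' @param mode `"conventional"` or `"malignancy"`.
#' @param image Optional grayscale image for the overlay, same size as the
#'   heat raster.
#' @param alpha Blend weight of the heat colors over the image.
#' @return An `H x W x 3` RGB array in `[0, 1]`.
#' @export
render_heatmap <- function(map, mode = c("conventional", "malignancy"),
                           image = NULL, alpha = 0.45) {
  mode <- match.arg(mode)
  v <- heat_values(map)
  stopifnot(all(is.finite(v)))
  if (mode == "conventional") {
    v <- pmax(v, 0)
    if (max(v) > 0) v <- v / max(v)
    ramp <- grDevices::colorRamp(
      c("black", "#400000", "#a00000", "#ff4500", "#ffa500", "#ffff00"))
  } else {
    v <- pmin(pmax(v, 0), 1)
    # diverging blue -> red anchors chosen so warmth (R - B) rises monotonically
    ramp <- grDevices::colorRamp(
      c("#0000a0", "#3060c0", "#70a0d0", "#e8e8b0", "#f08030", "#ff2020"))
  }
  cols <- ramp(as.vector(v)) / 255
  rgb <- array(0, c(nrow(v), ncol(v), 3))
  for (ch in 1:3) rgb[, , ch] <- matrix(cols[, ch], nrow(v), ncol(v))
  if (!is.null(image)) {
    stopifnot(all(dim(image) == dim(v)))
    for (ch in 1:3) {
      rgb[, , ch] <- (1 - alpha) * image + alpha * rgb[, , ch]
    }
  }
  rgb
}
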