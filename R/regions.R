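# Equal-area nested level-set partitioning of a nodular CAM.
#
# The nodular support is {CAM > 0} with area N. The lowest-valued floor(N/k)
# pixels are peeled off as region I (outermost), the next block as region II,
# and so on up to region k (innermost, hottest); the N mod k leftover pixels
# are assigned one each to the innermost regions so the hot core is never the
# smallest. For all-distinct values this is exactly value-quantile binning of
# the positive pixels. Ties are broken by raster scan order (column-major
# linear index), deterministically.

#' Partition a CAM into k equal-area nested regions
#'
#' @param cam_raster Numeric matrix (e.g. an upsampled, clamped CAM); pixels
#'   with value > 0 form the nodular support.
#' @param k Number of regions (default 5: labels 1 = region I, outermost,
#'   coolest ... 5 = region V, innermost, hottest).
#' @return An object of class `region_partition`: `labels` (integer raster,
#'   0 = background), `areas` (pixel counts per region), `thresholds`
#'   (lower level-set cut value of each region) and `N` (total support area).
#' @export
segment_equal_areas <- function(cam_raster, k = 5L) {
  stopifnot(is.matrix(cam_raster), k >= 1L)
  v <- as.vector(cam_raster)
  pos <- which(v > 0)
  N <- length(pos)
  if (N < k) {
    stop(sprintf("degenerate input: only %d positive pixels for k = %d regions",
                 N, k), call. = FALSE)
  }
  ord <- pos[order(v[pos], pos)]
  base <- N %/% k
  sizes <- rep(base, k)
  rem <- N %% k
  if (rem > 0) sizes[seq(k - rem + 1L, k)] <- base + 1L
  labels_vec <- integer(length(v))
  labels_vec[ord] <- rep.int(seq_len(k), times = sizes)
  labels <- matrix(labels_vec, nrow(cam_raster), ncol(cam_raster))
  starts <- cumsum(c(1L, sizes[-k]))
  thresholds <- v[ord[starts]]
  structure(list(labels = labels, areas = sizes, thresholds = thresholds,
                 N = N, k = k),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> N = %d support pixels in %d regions: %s\n",
              x$N, x$k, paste(x$areas, collapse = ", ")))
  invisible(x)
}

#' Extract the mask of one region
#'
#' @param partition A `region_partition`.
#' @param region Region index (1 = outermost ... k = innermost) or `"all"`
#'   for the full nodular support.
#' @return Logical matrix.
#' @export
region_mask <- function(partition, region) {
  stopifnot(inherits(partition, "region_partition"))
  if (identical(region, "all")) return(partition$labels > 0L)
  stopifnot(region >= 1, region <= partition$k)
  partition$labels == as.integer(region)
}

#' Binary masks above a sweep of heat thresholds
#'
#' Returns `{CAM >= t}` restricted to the nodular support `{CAM > 0}` for
#' each threshold, so the mask at threshold 0 is the full support and masks
#' shrink monotonically as the threshold rises.
#'
#' @param cam_raster Numeric matrix.
#' @param thresholds Ascending numeric vector of heat-intensity cuts.
#' @return List of logical matrices, one per threshold.
#' @export
threshold_sweep <- function(cam_raster, thresholds) {
  stopifnot(is.matrix(cam_raster))
  if (is.unsorted(thresholds)) {
    stop("thresholds must be ascending", call. = FALSE)
  }
  support <- cam_raster > 0
  lapply(thresholds, function(t) (cam_raster >= t) & support)
}
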