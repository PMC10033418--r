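#' Classical instance segmentation of a grayscale volume
#'
#' The non-learning labelling pipeline used for whole-cell/organelle
#' labelling: median filter (3x3x3), optional percentile contrast rescaling,
#' threshold (Otsu on the filtered histogram by default, or a fixed value),
#' optional separation of touching objects by a distance-transform watershed,
#' and connected-component labelling into dense positive instance ids.
#'
#' @param volume grayscale [volume_grid()].
#' @param object `"bright"` (foreground above threshold) or `"dark"`.
#' @param threshold fixed threshold; `NULL` for automatic (Otsu).
#' @param median_filter apply the 3x3x3 median prefilter.
#' @param contrast optional `c(lo, hi)` quantiles for percentile rescaling
#'   before thresholding (e.g. `c(0.01, 0.99)`); `NULL` disables.
#' @param separate split touching objects with a watershed on the
#'   anisotropy-aware distance transform.
#' @param connectivity final component labelling connectivity.
#' @param marker_radius neighbourhood radius (voxels) for watershed seed
#'   detection (local maxima of the distance transform).
#' @return [volume_grid()] of instance labels.  An all-background threshold
#'   result returns an empty labelling with a warning.
#' @export
classical_instance_segmentation <- function(volume,
                                            object = c("bright", "dark"),
                                            threshold = NULL,
                                            median_filter = TRUE,
                                            contrast = NULL,
                                            separate = TRUE,
                                            connectivity = 26,
                                            marker_radius = 3) {
  object <- match.arg(object)
  volume <- as_volume_grid(volume)
  v <- volume$data
  dm <- dim(v)
  if (median_filter) v <- median3_cpp(as.numeric(v), dm)
  if (!is.null(contrast)) {
    q <- quantile(v, contrast, names = FALSE)
    if (q[2] > q[1]) v <- pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  }
  thr <- if (is.null(threshold)) otsu_threshold(v) else threshold
  mask <- if (object == "bright") v > thr else v < thr
  dim(mask) <- dm
  if (!any(mask)) {
    warning("all-background after thresholding: returning empty labelling")
    return(volume_grid(array(0L, dm), volume$voxel_size, volume$origin))
  }
  if (separate) {
    edt <- sqrt(edt_sq_cpp(as.logical(!mask), dm, volume$voxel_size))
    edt[!mask] <- 0
    seeds <- local_maxima_cpp(edt, dm, as.integer(marker_radius))
    markers <- cc_label_cpp(seeds, dm, 26L)
    lab <- watershed_flood_cpp(edt, markers, as.logical(mask), dm)
    # voxels unreachable from any seed (shouldn't happen in practice)
    left <- mask & lab == 0
    if (any(left)) {
      extra <- cc_label_cpp(as.logical(left), dm, as.integer(connectivity))
      lab[left] <- extra[left] + max(lab)
    }
  } else {
    lab <- cc_label_cpp(as.logical(mask), dm, as.integer(connectivity))
  }
  volume_grid(lab, volume$voxel_size, volume$origin)
}
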