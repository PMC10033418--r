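#' Time-lapse series of binary mitochondrial masks
#'
#' Frame 1 is the reference configuration against which all later frames are
#' compared; frames are uniformly spaced `dt_s` seconds apart.
#'
#' @param frames list of same-shape binary matrices, length `>= 2`.
#' @param dt_s inter-frame interval, seconds (20 in the imaging protocol).
#' @return object of class `motility_series`.
#' @export
motility_series <- function(frames, dt_s = 20) {
  if (!is.list(frames) || length(frames) < 2) stop("need >= 2 frames")
  d1 <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), d1)) stop("all frames must have the same shape")
    if (!all(f %in% c(0, 1) | is.logical(f))) stop("frames must be binary")
  }
  frames <- lapply(frames, function(f) f > 0)
  structure(list(frames = frames, dt_s = dt_s,
                 times_s = (seq_along(frames) - 1) * dt_s),
            class = "motility_series")
}

#' Threshold a grayscale time-lapse into a binary motility series
#'
#' Mirrors the ImageJ preprocessing order used for TMRE time-lapse data:
#' rolling-ball-style background subtraction (grayscale opening with a disc),
#' then a per-frame threshold (Otsu by default, or a fixed value, optionally
#' shared from frame 1).
#'
#' @param images 3D array `(frame, y, x)` or list of matrices, `>= 2` frames.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed threshold value used when `method = "fixed"`.
#' @param background_radius disc radius (pixels) for background subtraction;
#'   `NULL` disables it.
#' @param shared_threshold reuse frame 1's automatic threshold for all frames.
#' @param dt_s inter-frame interval, seconds.
#' @return a [motility_series()].  Degenerate (constant) frames threshold to
#'   empty masks with a warning.
#' @export
binarize_series <- function(images, method = c("otsu", "fixed"), fixed = 0.5,
                            background_radius = NULL, shared_threshold = FALSE,
                            dt_s = 20) {
  method <- match.arg(method)
  if (is.array(images) && length(dim(images)) == 3)
    images <- lapply(seq_len(dim(images)[1]), function(i) images[i, , ])
  if (!is.list(images) || length(images) < 2) stop("need >= 2 frames")
  thr1 <- NULL
  masks <- vector("list", length(images))
  for (i in seq_along(images)) {
    fr <- images[[i]]
    if (!is.null(background_radius) && background_radius > 0) {
      brush <- EBImage::makeBrush(2 * background_radius + 1, shape = "disc")
      bg <- EBImage::opening(EBImage::Image(fr), brush)
      fr <- fr - as.matrix(bg@.Data)
    }
    if (method == "fixed") {
      thr <- fixed
    } else if (shared_threshold && !is.null(thr1)) {
      thr <- thr1
    } else {
      if (diff(range(fr)) == 0) {
        warning(sprintf("frame %d is constant; thresholding to an empty mask", i))
        masks[[i]] <- matrix(FALSE, nrow(fr), ncol(fr))
        next
      }
      thr <- otsu_threshold(fr)
      if (is.null(thr1)) thr1 <- thr
    }
    masks[[i]] <- fr > thr
  }
  motility_series(masks, dt_s = dt_s)
}

#' Per-frame displacement ratios against the reference frame
#'
#' For each frame `n >= 2`, `overlap_area(n)` is the pixel count of the
#' intersection with frame 1, `travel_area(n) = mitochondria_area(n) -
#' overlap_area(n)`, and the displacement ratio is
#' `ratio(n) = travel_area(n) / overlap_area(n)`.  Frames with zero overlap
#' have no defined ratio and are recorded as excluded rather than fabricated.
#'
#' @param series a [motility_series()].
#' @return object of class `motility_result`: a table of per-frame areas and
#'   ratios, exclusions with reasons, and (after [motility_slope()]) the
#'   regression slope and intercept.
#' @export
displacement_ratios <- function(series) {
  stopifnot(inherits(series, "motility_series"))
  ref <- series$frames[[1]]
  if (!any(ref)) stop("reference frame (frame 1) is empty: no overlap is definable")
  n <- length(series$frames)
  tab <- data.frame(frame = 2:n, time_s = series$times_s[2:n],
                    area_px = NA_real_, overlap_px = NA_real_,
                    travel_px = NA_real_, ratio = NA_real_,
                    excluded = FALSE, reason = "", stringsAsFactors = FALSE)
  for (i in 2:n) {
    m <- series$frames[[i]]
    ov <- sum(m & ref)
    ar <- sum(m)
    row <- i - 1
    tab$area_px[row] <- ar
    tab$overlap_px[row] <- ov
    tab$travel_px[row] <- ar - ov
    if (ov == 0) {
      tab$excluded[row] <- TRUE
      tab$reason[row] <- "zero overlap"
      warning(sprintf("frame %d has zero overlap with the reference; excluded", i))
    } else {
      tab$ratio[row] <- (ar - ov) / ov
    }
  }
  structure(list(ratios = tab, dt_s = series$dt_s,
                 slope = NA_real_, intercept = NA_real_,
                 excluded_frames = tab$frame[tab$excluded]),
            class = "motility_result")
}

#' Motility readout: slope of the displacement-ratio regression
#'
#' Ordinary least squares fit of `ratio = a * time + b` over the retained
#' frames; the slope `a` (per second) is the motility readout.
#'
#' @param result a `motility_result` from [displacement_ratios()].
#' @return the result with `slope` (s^-1) and `intercept` filled in.
#' @export
motility_slope <- function(result) {
  stopifnot(inherits(result, "motility_result"))
  keep <- !result$ratios$excluded
  if (sum(keep) < 2)
    stop(sprintf("fewer than 2 retained frames for the regression (excluded: %s)",
                 paste(result$ratios$frame[result$ratios$excluded], collapse = ", ")))
  fit <- lm(ratio ~ time_s, data = result$ratios[keep, ])
  result$slope <- unname(coef(fit)[2])
  result$intercept <- unname(coef(fit)[1])
  result
}

#' @export
print.motility_result <- function(x, ...) {
  cat(sprintf("<motility_result> %d frames, slope = %.6g s^-1, intercept = %.6g\n",
              nrow(x$ratios) + 1, x$slope, x$intercept))
  if (length(x$excluded_frames))
    cat("  excluded frames:", paste(x$excluded_frames, collapse = ", "), "\n")
  invisible(x)
}
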