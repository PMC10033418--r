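#' Synthetic time-lapse motility series with known displacement velocity
#'
#' Emulates the live-cell motility protocol: a field of view imaged at fixed
#' intervals (20 s by default, 10 frames).  Frame 1 is the reference
#' configuration; frame `n` is the reference translated by
#' `velocity * (n - 1)` pixels along `direction` (sub-pixel displacements are
#' rasterized by rounding).  Optionally renders noisy grayscale images from
#' the masks (TMRE-like bright blobs) for testing thresholding.
#'
#' @param mask reference binary matrix, or a list
#'   `list(shape = c(h, w), n_blobs, blob_radius)` from which a random blob
#'   mask is drawn.
#' @param velocity_px_per_frame displacement per frame in pixels, `>= 0`.
#' @param n_frames number of frames, `>= 2`.
#' @param dt_s inter-frame interval in seconds.
#' @param direction unit-ish vector `(dy, dx)`; scaled internally.
#' @param noise_sd if `> 0`, also return grayscale frames
#'   `amplitude * mask + N(0, noise_sd)`.
#' @param amplitude foreground intensity of the grayscale rendering.
#' @param seed RNG seed (blob placement and noise).
#' @return list with `series` (a [motility_series()]), `true_velocity`,
#'   `times_s`, and `images` (3D array `(frame, y, x)`) when `noise_sd > 0`.
#' @export
generate_motility_series <- function(mask = list(shape = c(64, 64), n_blobs = 6,
                                                 blob_radius = 3),
                                     velocity_px_per_frame = 1,
                                     n_frames = 10, dt_s = 20,
                                     direction = c(0, 1),
                                     noise_sd = 0, amplitude = 1, seed = 1) {
  if (n_frames < 2) stop("need at least 2 frames")
  if (velocity_px_per_frame < 0) stop("velocity must be >= 0")
  set.seed(seed)
  if (is.list(mask)) {
    h <- mask$shape[1]; w <- mask$shape[2]
    ref <- matrix(FALSE, h, w)
    for (b in seq_len(mask$n_blobs)) {
      cy <- runif(1, mask$blob_radius + 1, h * 0.6)
      cx <- runif(1, mask$blob_radius + 1, w * 0.6)
      yy <- matrix(seq_len(h), h, w)
      xx <- matrix(seq_len(w), h, w, byrow = TRUE)
      ref <- ref | ((yy - cy)^2 + (xx - cx)^2 <= mask$blob_radius^2)
    }
  } else {
    ref <- mask > 0
  }
  if (!any(ref)) stop("reference mask is empty")
  dirn <- direction / sqrt(sum(direction^2))
  h <- nrow(ref); w <- ncol(ref)
  frames <- vector("list", n_frames)
  frames[[1]] <- ref
  for (f in 2:n_frames) {
    off <- round(velocity_px_per_frame * (f - 1) * dirn)
    shifted <- matrix(FALSE, h, w)
    src <- which(ref, arr.ind = TRUE)
    ty <- src[, 1] + off[1]
    tx <- src[, 2] + off[2]
    keep <- ty >= 1 & ty <= h & tx >= 1 & tx <= w
    if (!any(keep))
      stop(sprintf("object translated fully out of frame at frame %d", f))
    shifted[cbind(ty[keep], tx[keep])] <- TRUE
    frames[[f]] <- shifted
  }
  out <- list(series = motility_series(frames, dt_s = dt_s),
              true_velocity = velocity_px_per_frame,
              times_s = (seq_len(n_frames) - 1) * dt_s)
  if (noise_sd > 0) {
    imgs <- array(0, c(n_frames, h, w))
    for (f in seq_len(n_frames))
      imgs[f, , ] <- amplitude * frames[[f]] + rnorm(h * w, 0, noise_sd)
    out$images <- imgs
  }
  out
}
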