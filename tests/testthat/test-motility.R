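square_series <- function(velocity, n_frames = 10, h = 24, w = 64) {
  ref <- matrix(FALSE, h, w)
  ref[8:17, 3:12] <- TRUE
  generate_motility_series(ref, velocity_px_per_frame = velocity,
                           n_frames = n_frames)$series
}

test_that("a static series gives zero ratios and exactly zero slope", {
  s <- square_series(0)
  res <- motility_slope(displacement_ratios(s))
  expect_true(all(res$ratios$ratio == 0))
  expect_identical(res$slope, 0)
  expect_identical(res$intercept, 0)
})

test_that("translated-square ratios match direct pixel bookkeeping", {
  s <- square_series(2, n_frames = 3)
  res <- displacement_ratios(s)
  # 10x10 square moving 2 px/frame: frame 2 overlap 80 travel 20; frame 3: 60/40
  expect_equal(res$ratios$overlap_px, c(80, 60))
  expect_equal(res$ratios$travel_px, c(20, 40))
  expect_equal(res$ratios$ratio, c(0.25, 2 / 3))
})

test_that("the regression slope equals a closed-form least-squares fit", {
  s <- square_series(1, n_frames = 10)
  res <- motility_slope(displacement_ratios(s))
  t <- res$ratios$time_s; y <- res$ratios$ratio
  slope_cf <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
  expect_equal(res$slope, slope_cf, tolerance = 1e-12)
  expect_equal(res$intercept, mean(y) - slope_cf * mean(t), tolerance = 1e-12)
  # an exact line is recovered exactly
  fake <- res
  fake$ratios$ratio <- 0.01 * fake$ratios$time_s
  fit <- motility_slope(fake)
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_lt(abs(fit$intercept), 1e-12)
})

test_that("zero-overlap frames are excluded, never fabricated", {
  ref <- matrix(FALSE, 12, 60); ref[4:9, 2:7] <- TRUE
  frames <- list(ref)
  for (n in 2:6) {
    f <- matrix(FALSE, 12, 60)
    off <- (n - 1) * 8                      # disjoint from frame 4 on
    f[4:9, (2:7) + off] <- TRUE
    frames[[n]] <- f
  }
  s <- motility_series(frames)
  expect_warning(res <- displacement_ratios(s), "zero overlap")
  expect_true(all(res$ratios$excluded[res$ratios$overlap_px == 0]))
  expect_true(all(res$ratios$reason[res$ratios$excluded] == "zero overlap"))
  expect_true(all(is.na(res$ratios$ratio[res$ratios$excluded])))
  # empty reference is an error
  empty <- motility_series(list(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4)))
  expect_error(displacement_ratios(empty), "reference frame")
  # all frames excluded but one -> too few points for the regression
  s2 <- motility_series(list(ref, frames[[6]], frames[[5]]))
  suppressWarnings(r2 <- displacement_ratios(s2))
  expect_error(motility_slope(r2), "fewer than 2")
})

test_that("a single global offset yields constant ratios and zero slope", {
  ref <- matrix(FALSE, 20, 30); ref[5:14, 3:12] <- TRUE
  sh <- matrix(FALSE, 20, 30); sh[5:14, 6:15] <- TRUE
  frames <- c(list(ref), rep(list(sh), 5))
  res <- motility_slope(displacement_ratios(motility_series(frames)))
  expect_equal(diff(range(res$ratios$ratio)), 0)
  expect_equal(res$slope, 0, tolerance = 1e-15)
})

test_that("the slope is strictly increasing in planted velocity", {
  # 30x30 object so overlap is retained in every frame at every velocity
  ref <- matrix(FALSE, 40, 80)
  ref[4:33, 3:32] <- TRUE
  slopes <- vapply(c(0, 0.5, 1, 1.5, 2), function(v) {
    s <- generate_motility_series(ref, v, n_frames = 10)$series
    motility_slope(displacement_ratios(s))$slope
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("ratios depend only on frames 1 and n (exchange property)", {
  s <- square_series(1.5, n_frames = 6)
  res <- displacement_ratios(s)
  perm <- c(1, 4, 2, 6, 3, 5)
  sp <- motility_series(s$frames[perm], dt_s = s$dt_s)
  rp <- displacement_ratios(sp)
  expect_equal(rp$ratios$ratio, res$ratios$ratio[perm[-1] - 1])
  # regression changes only through the time pairing
  f1 <- motility_slope(rp)
  fit <- lm(res$ratios$ratio[perm[-1] - 1] ~ rp$ratios$time_s)
  expect_equal(f1$slope, unname(coef(fit)[2]), tolerance = 1e-12)
})

test_that("thresholding recovers generator truth masks from noisy frames", {
  gen <- generate_motility_series(mask = list(shape = c(64, 64), n_blobs = 6,
                                              blob_radius = 4),
                                  velocity_px_per_frame = 1, n_frames = 6,
                                  noise_sd = 0.2, amplitude = 1, seed = 2)
  s <- binarize_series(gen$images, method = "otsu")
  agree <- mean(mapply(function(a, b) mean(a == b), s$frames, gen$series$frames))
  expect_gte(agree, 0.95)
  # already-binary input with a fixed 0.5 threshold is unchanged
  sb <- binarize_series(lapply(gen$series$frames, function(f) f * 1),
                        method = "fixed", fixed = 0.5)
  expect_identical(sb$frames, gen$series$frames)
  # constant frames threshold to empty masks with a warning
  expect_warning(binarize_series(list(matrix(0.3, 8, 8),
                                      matrix(runif(64), 8, 8))),
                 "constant")
})
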