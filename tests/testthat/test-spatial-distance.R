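test_that("moment fitting recovers rasterized ellipse parameters", {
  mk <- function(a, b, th, h = 220, w = 220, cy = 100, cx = 110) {
    yy <- matrix(seq_len(h) - 1, h, w)
    xx <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
    u <- cos(th) * (xx - cx) + sin(th) * (yy - cy)
    v <- -sin(th) * (xx - cx) + cos(th) * (yy - cy)
    (u / a)^2 + (v / b)^2 <= 1
  }
  e <- fit_nucleus_ellipse(mk(50, 30, 0))
  expect_lt(abs(e$a / 50 - 1), 0.02)
  expect_lt(abs(e$b / 30 - 1), 0.02)
  expect_lt(min(e$theta, pi - e$theta), 0.02)

  e30 <- fit_nucleus_ellipse(mk(50, 30, 30 * pi / 180))
  expect_lt(abs(e30$theta - 30 * pi / 180), pi / 180)

  disk <- fit_nucleus_ellipse(mk(40, 40, 0))
  expect_lt(abs(disk$a / disk$b - 1), 0.01)
  expect_true(disk$theta >= 0 && disk$theta < pi)

  expect_error(fit_nucleus_ellipse(matrix(FALSE, 5, 5)), "empty")
  line <- matrix(FALSE, 10, 10); line[4, ] <- TRUE
  expect_error(fit_nucleus_ellipse(line), "degenerate")
})

test_that("point-to-ellipse distance handles closed forms and boundary points", {
  e <- ellipse_shape(c(1, -2), 3, 3, theta = 0.4)   # circle
  p <- c(7, 1)
  expect_equal(point_to_ellipse_distance(p, e)$distance,
               abs(sqrt(sum((p - c(1, -2))^2)) - 3), tolerance = 1e-12)

  e2 <- ellipse_shape(c(0, 0), 2, 1)
  r <- point_to_ellipse_distance(c(2, 1), e2)
  expect_equal(r$distance, point_to_ellipse_distance_oracle(c(2, 1), e2),
               tolerance = 1e-6)
  # centre: distance = semi-minor, closest point on the minor axis
  rc <- point_to_ellipse_distance(c(0, 0), e2)
  expect_equal(rc$distance, 1)
  expect_equal(unname(rc$closest_point), c(0, 1), tolerance = 1e-12)
  # boundary points map to themselves
  bp <- sample_ellipse_boundary(ellipse_shape(c(3, 2), 4, 1.5, 1.1), 17,
                                random = TRUE, seed = 5)
  for (i in seq_len(nrow(bp))) {
    ri <- point_to_ellipse_distance(bp[i, ], ellipse_shape(c(3, 2), 4, 1.5, 1.1))
    expect_lt(ri$distance, 1e-9)
    expect_lt(max(abs(ri$closest_point - bp[i, ])), 1e-7)
  }
})

test_that("the quartic solver matches the dense oracle over random cases", {
  set.seed(17)
  worst <- 0
  for (i in 1:200) {
    a <- runif(1, 0.5, 40); b <- runif(1, 0.05, 1) * a
    e <- ellipse_shape(runif(2, -20, 20), a, b, runif(1, 0, pi))
    p <- runif(2, -80, 80)
    r <- point_to_ellipse_distance(p, e)
    expect_lte(r$n_candidates, 4)
    o <- point_to_ellipse_distance_oracle(p, e)
    worst <- max(worst, abs(r$distance - o) / max(o, 1e-12))
    # the closest point satisfies the implicit equation
    u <- cos(e$theta) * (r$closest_point[1] - e$center[1]) +
      sin(e$theta) * (r$closest_point[2] - e$center[2])
    v <- -sin(e$theta) * (r$closest_point[1] - e$center[1]) +
      cos(e$theta) * (r$closest_point[2] - e$center[2])
    expect_lt(abs((u / a)^2 + (v / b)^2 - 1), 1e-9)
  }
  expect_lt(worst, 1e-6)
})

test_that("the distance is invariant under rigid motions of point and ellipse", {
  set.seed(23)
  e <- ellipse_shape(c(2, 1), 5, 2, 0.6)
  p <- c(9, -3)
  d0 <- point_to_ellipse_distance(p, e)$distance
  for (i in 1:10) {
    phi <- runif(1, 0, 2 * pi); tr <- runif(2, -50, 50)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    e2 <- ellipse_shape(as.numeric(R %*% e$center + tr), e$a, e$b, e$theta + phi)
    p2 <- as.numeric(R %*% p + tr)
    expect_equal(point_to_ellipse_distance(p2, e2)$distance, d0, tolerance = 1e-9)
  }
})

test_that("the anisotropic distance transform equals brute force on small grids", {
  set.seed(31)
  for (rep in 1:3) {
    dm <- c(12, 14, 10); sp <- c(50, 5, 5)
    f <- array(runif(prod(dm)) < 0.04, dm)
    if (!any(f)) f[5, 5, 5] <- TRUE
    got <- mitoscape:::edt_sq_cpp(as.logical(f), dm, sp)
    feat <- which(f, arr.ind = TRUE)
    for (q in sample(prod(dm), 150)) {
      ai <- arrayInd(q, dm)
      d2 <- min(((ai[1] - feat[, 1]) * sp[1])^2 + ((ai[2] - feat[, 2]) * sp[2])^2 +
                  ((ai[3] - feat[, 3]) * sp[3])^2)
      expect_equal(got[q], d2, tolerance = 1e-9)
    }
  }
})

test_that("3D mitochondrion-to-nucleus distances match analytic geometry", {
  dm <- c(30, 120, 120); vs <- c(50, 5, 5)
  nuc <- array(0L, dm)
  nuc[rasterize_sphere(dm, vs, c(725, 300, 300), 200)] <- 1L
  inst <- array(0L, dm)
  inst[15, 61, 101] <- 1L           # centre (700, 300, 500): radius 500 from centre
  d <- mito_nucleus_distances_3d(volume_grid(inst, vs), volume_grid(nuc, vs))
  rad <- sqrt((700 - 725)^2 + 0^2 + (500 - 300)^2)
  expect_lt(abs(d$distance_um * 1000 - (rad - 200)), sqrt(sum(vs^2)))

  # face-adjacent instance: one voxel step in x
  inst2 <- array(0L, dm)
  edge_x <- max(which(nuc[15, 61, ] > 0))
  inst2[15, 61, edge_x + 1L] <- 1L
  d2 <- mito_nucleus_distances_3d(volume_grid(inst2, vs), volume_grid(nuc, vs))
  expect_equal(d2$distance_um * 1000, 5)

  # instance inside the nucleus footprint -> 0
  inst3 <- array(0L, dm); inst3[15, 61, 61] <- 1L
  expect_equal(mito_nucleus_distances_3d(volume_grid(inst3, vs),
                                         volume_grid(nuc, vs))$distance_um, 0)
  expect_error(mito_nucleus_distances_3d(volume_grid(inst3, vs),
                                         volume_grid(array(0L, dm), vs)),
               "empty nucleus")
})

test_that("perinuclear placement yields smaller median nucleus distances", {
  mk <- function(mode, seed) {
    # full-size grid so the dispersed cytoplasm is genuinely farther than the shell
    sp <- scene_spec(n_mitochondria = 8, n_lipid_droplets = 0, placement = mode,
                     shell_width = 300,
                     mito = list(length_mean_um = 0.4, length_sd_um = 0.1),
                     seed = seed)
    sc <- generate_cell_volume(sp)
    mito <- sc$truth$instance_volume
    mito$data[sc$truth$class_volume$data != 2L] <- 0L
    nuc <- sc$truth$class_volume
    nuc$data <- nuc$data == 1L
    median(mito_nucleus_distances_3d(mito, nuc)$distance_um)
  }
  expect_lt(mk("perinuclear", 41), mk("dispersed", 41))
})
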