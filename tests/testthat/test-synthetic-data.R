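test_that("an organelle-free scene contains exactly the nucleus", {
  sp <- small_scene_spec(n_mito = 0, n_ld = 0)
  sc <- generate_cell_volume(sp)
  tab <- sc$truth$instance_table
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$class, 1L)
  expect_setequal(unique(as.vector(sc$truth$class_volume$data)), c(0L, 1L))
})

test_that("the generator is bit-identical under a fixed seed", {
  sp <- small_scene_spec(seed = 9)
  a <- generate_cell_volume(sp)
  b <- generate_cell_volume(sp)
  expect_identical(a$grayscale$data, b$grayscale$data)
  expect_identical(a$truth$instance_volume$data, b$truth$instance_volume$data)
  expect_identical(a$truth$instance_table, b$truth$instance_table)
})

test_that("capsule instance volumes match the analytic capsule formula", {
  sp <- scene_spec(grid_shape = c(64, 512, 512),
                   n_mitochondria = 25, n_lipid_droplets = 0,
                   mito = list(radius = 100, length_mean_um = 1,
                               length_sd_um = 0, curvature = 0),
                   seed = 7)
  sc <- generate_cell_volume(sp)
  m <- subset(sc$truth$instance_table, class == 2)
  expect_equal(nrow(m), 25L)
  analytic <- pi * 0.1^2 * m$axis_length_um + 4 / 3 * pi * 0.1^3
  expect_lt(max(abs(m$volume_um3 / analytic - 1)), 0.10)
  # table volumes are exactly voxel count x voxel volume
  expect_equal(m$volume_um3, m$voxel_count * voxel_volume_um3(sp$voxel_size))
})

test_that("instance volumes are conserved and classes consistent", {
  sc <- generate_cell_volume(small_scene_spec(seed = 4))
  inst <- sc$truth$instance_volume$data
  cls <- sc$truth$class_volume$data
  tab <- sc$truth$instance_table
  expect_equal(sum(tab$voxel_count), sum(inst > 0))
  # every nonzero instance voxel carries its instance's class
  for (i in seq_len(nrow(tab))) {
    w <- inst == tab$instance_id[i]
    expect_true(all(cls[w] == tab$class[i]))
  }
  # dense ids
  expect_identical(sort(unique(inst[inst > 0])), seq_len(nrow(tab)))
})

test_that("doubling the section step doubles every physical instance volume", {
  sc <- generate_cell_volume(small_scene_spec(seed = 5))
  inst <- sc$truth$instance_volume
  counts <- tabulate(inst$data[inst$data > 0])
  v1 <- counts * voxel_volume_um3(inst$voxel_size)
  inst2 <- volume_grid(inst$data, inst$voxel_size * c(2, 1, 1))
  v2 <- counts * voxel_volume_um3(inst2$voxel_size)
  expect_equal(v2, 2 * v1)
  expect_equal(v1, sc$truth$instance_table$volume_um3)
})

test_that("a crowded scene fails with an explicit placement error", {
  sp <- scene_spec(grid_shape = c(16, 96, 96),
                   nucleus = list(semi_axes = c(250, 180, 180)),
                   n_mitochondria = 200, n_lipid_droplets = 0,
                   max_retries = 25, seed = 1)
  expect_error(generate_cell_volume(sp), "mitochondrion")
})

test_that("motility frames follow the planted constant-velocity translation", {
  ref <- matrix(FALSE, 16, 16)
  ref[4:13, 2:11] <- TRUE
  gen <- generate_motility_series(ref, velocity_px_per_frame = 2, n_frames = 3)
  f1 <- gen$series$frames[[1]]
  f3 <- gen$series$frames[[3]]
  expect_identical(which(f3, arr.ind = TRUE)[, 2] - 4L,
                   which(f1, arr.ind = TRUE)[, 2])
  # zero velocity: all frames identical
  st <- generate_motility_series(ref, 0, n_frames = 10)
  for (f in st$series$frames) expect_identical(f, ref)
  # protocol timing: 10 frames every 20 s -> 0, 20, ..., 180 s
  expect_equal(st$times_s, seq(0, 180, by = 20))
  # object leaving the field is an explicit error
  expect_error(generate_motility_series(ref, 8, n_frames = 10), "out of frame")
})

test_that("ellipse boundary samples lie exactly on the ellipse", {
  e <- ellipse_shape(c(0, 0), 1, 1)
  p <- sample_ellipse_boundary(e, 33, random = TRUE, seed = 2)
  expect_lt(max(abs(sqrt(rowSums(p^2)) - 1)), 1e-12)

  e2 <- ellipse_shape(c(0, 0), 3, 2)
  p4 <- sample_ellipse_boundary(e2, 4)
  expect_equal(unname(p4), rbind(c(3, 0), c(0, 2), c(-3, 0), c(0, -2)),
               tolerance = 1e-12)

  e3 <- ellipse_shape(c(2, -1), 5, 2, theta = 0.7)
  p3 <- sample_ellipse_boundary(e3, 50, random = TRUE, seed = 8)
  # implicit quadratic form in the ellipse frame
  u <- cos(e3$theta) * (p3[, 1] - 2) + sin(e3$theta) * (p3[, 2] + 1)
  v <- -sin(e3$theta) * (p3[, 1] - 2) + cos(e3$theta) * (p3[, 2] + 1)
  expect_lt(max(abs((u / 5)^2 + (v / 2)^2 - 1)), 1e-10)
})
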