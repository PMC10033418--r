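test_that("connectivity semantics separate or join corner-touching cubes", {
  a <- array(0L, c(8, 8, 8))
  a[2:3, 2:3, 2:3] <- 1L
  a[4:5, 4:5, 4:5] <- 1L      # touches the first cube only at a corner
  vg <- volume_grid(a, c(1, 1, 1))
  expect_equal(max(label_components(vg, connectivity = 6)$data), 2L)
  expect_equal(max(label_components(vg, connectivity = 26)$data), 1L)
  b <- array(0L, c(8, 8, 8)); b[1:2, 1:2, 1:2] <- 1L; b[6:7, 6:7, 6:7] <- 1L
  expect_equal(max(label_components(volume_grid(b, c(1, 1, 1)), 6)$data), 2L)
  expect_error(label_components(volume_grid(array(2L, c(2, 2, 2)), c(1, 1, 1))),
               "binary")
})

test_that("labelling a known scene recovers the planted instance count exactly", {
  sc <- generate_cell_volume(small_scene_spec(n_mito = 6, n_ld = 0, seed = 21))
  tab <- sc$truth$instance_table
  mito_mask <- sc$truth$class_volume
  mito_mask$data <- mito_mask$data == 2L
  lab <- label_components(mito_mask)
  expect_equal(max(lab$data), sum(tab$class == 2))
  # conservation: instance voxels partition the foreground
  expect_equal(sum(tabulate(lab$data[lab$data > 0])), sum(mito_mask$data))
})

test_that("a voxelized ball is measured as a sphere", {
  vg <- make_ball(20)
  rec <- measure_components(vg)
  expect_equal(nrow(rec), 1)
  v_true <- 4 / 3 * pi * 20^3 * 1e-9
  expect_lt(abs(rec$volume_um3 / v_true - 1), 0.02)
  expect_gte(rec$sphericity, 0.97)
  expect_lte(rec$sphericity, 1.05)
})

test_that("capsule length approximates axis length plus both caps", {
  for (d in list(c(0, 0, 1), c(0, 1, 1), c(1, 8, 8))) {
    vg <- make_capsule(len_nm = 2000, r_nm = 100, dirv = d)
    rec <- measure_components(vg)
    expect_lt(abs(rec$length_um - 2.2) / 2.2, 0.10)
  }
})

test_that("sphericity decreases strictly along an elongating capsule family", {
  lens <- c(200, 600, 1200, 2400, 4000)
  psi <- vapply(lens, function(L)
    measure_components(make_capsule(len_nm = L, r_nm = 100))$sphericity,
    numeric(1))
  expect_true(all(diff(psi) < 0))
  expect_true(all(psi > 0 & psi <= 1.05))
})

test_that("measures scale correctly with voxel size and psi is invariant", {
  vg <- make_capsule(len_nm = 1200, r_nm = 100)
  r1 <- measure_components(vg)
  s <- 2          # power of two: the voxel arithmetic scales exactly
  vg2 <- volume_grid(vg$data, vg$voxel_size * s)
  r2 <- measure_components(vg2)
  expect_equal(r2$volume_um3, s^3 * r1$volume_um3, tolerance = 1e-10)
  expect_equal(r2$surface_area_um2, s^2 * r1$surface_area_um2, tolerance = 1e-6)
  expect_equal(r2$length_um, s * r1$length_um, tolerance = 1e-6)
  expect_equal(r2$sphericity, r1$sphericity, tolerance = 1e-6)
})

test_that("single-voxel instances get total (non-NaN) measures", {
  a <- array(0L, c(5, 5, 5)); a[3, 3, 3] <- 1L
  rec <- measure_components(volume_grid(a, c(50, 5, 5)))
  expect_equal(rec$voxel_count, 1L)
  expect_equal(rec$volume_um3, voxel_volume_um3(c(50, 5, 5)))
  expect_equal(rec$surface_area_um2, 2 * (50 * 5 + 5 * 5 + 50 * 5) * 1e-6)
  expect_equal(rec$length_um, 0.05)
  expect_true(is.finite(rec$sphericity))
})

test_that("density summaries integrate to one and find planted modes", {
  rec <- data.frame(length_um = c(rnorm(300, 0.5, 0.05), rnorm(300, 2, 0.1)))
  d <- summarize_distributions(rec, "length_um", bins = 40)
  w <- d$bin_right - d$bin_left
  expect_equal(sum(d$density * w), 1, tolerance = 1e-9)
  # bimodal: local maxima near the two planted means
  peaks <- d$bin_mid[order(d$density, decreasing = TRUE)[1:8]]
  expect_true(any(abs(peaks - 0.5) < 0.15))
  expect_true(any(abs(peaks - 2.0) < 0.3))

  one <- summarize_distributions(data.frame(v = rep(3, 10)), "v", bins = 5)
  expect_equal(sum(one$count > 0), 1)
  expect_equal(sum(one$density * (one$bin_right - one$bin_left)), 1)
  expect_error(summarize_distributions(data.frame(), "v"), "empty")
})
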