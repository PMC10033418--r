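test_that("two well-separated bright blobs give exactly two instances", {
  dm <- c(20, 40, 40)
  a <- array(0, dm)
  a[rasterize_sphere(dm, c(1, 1, 1), c(10, 10, 10), 5)] <- 1
  a[rasterize_sphere(dm, c(1, 1, 1), c(10, 28, 28), 5)] <- 1
  set.seed(2)
  a <- a + rnorm(prod(dm), 0, 0.05)
  lab <- classical_instance_segmentation(volume_grid(a, c(1, 1, 1)),
                                         object = "bright", separate = FALSE)
  expect_equal(length(setdiff(unique(as.vector(lab$data)), 0L)), 2L)
})

test_that("touching spheres are split by the distance-transform watershed", {
  dm <- c(40, 80, 80)
  a <- array(0, dm)
  # centres 18 px apart with radius 12: overlap well under one radius
  a[rasterize_sphere(dm, c(1, 1, 1), c(20, 30, 40), 12)] <- 1
  a[rasterize_sphere(dm, c(1, 1, 1), c(20, 48, 40), 12)] <- 1
  set.seed(5)
  vg <- volume_grid(a + rnorm(prod(dm), 0, 0.05), c(1, 1, 1))
  merged <- classical_instance_segmentation(vg, object = "bright", separate = FALSE)
  expect_equal(length(setdiff(unique(as.vector(merged$data)), 0L)), 1L)
  split <- classical_instance_segmentation(vg, object = "bright", separate = TRUE)
  expect_equal(length(setdiff(unique(as.vector(split$data)), 0L)), 2L)
})

test_that("instance count on a synthetic cell volume matches the ground truth", {
  # uniform dark organelles on bright background so one threshold captures all
  # planted droplet contacts off: contact pairs are deliberately touching and
  # would (correctly) merge under connected components
  sp <- small_scene_spec(seed = 12, pdm_fraction = 0,
                         intensity = list(nucleus = 0.2, mitochondria = 0.2,
                                          lipid_droplet = 0.2, noise_sd = 0.03))
  sc <- generate_cell_volume(sp)
  lab <- classical_instance_segmentation(sc$grayscale, object = "dark",
                                         separate = FALSE)
  expect_equal(length(setdiff(unique(as.vector(lab$data)), 0L)),
               nrow(sc$truth$instance_table))
})

test_that("an all-background threshold result warns and returns empty labels", {
  set.seed(3)
  vg <- volume_grid(array(rnorm(10^3, 0.5, 0.01), c(10, 10, 10)), c(1, 1, 1))
  expect_warning(
    lab <- classical_instance_segmentation(vg, object = "bright", threshold = 2),
    "all-background")
  expect_true(all(lab$data == 0L))
})
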