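# A hand-planted contact scene: one nucleus slab, one LD sphere, and three
# mitochondria spheres at controlled surface distances from the LD.
planted_contact_scene <- function(gaps_nm = c(20, 40, 300), vs = c(50, 5, 5)) {
  dm <- c(24, 260, 400)
  nuc <- array(0L, dm)
  nuc[, , 1:20] <- 1L                       # slab: surface at x index 20
  ld_c <- c(575, 650, 800)
  ld_r <- 150
  lds <- array(0L, dm)
  lds[rasterize_sphere(dm, vs, ld_c, ld_r)] <- 1L
  mito <- array(0L, dm)
  r_m <- 80
  dirs <- list(c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))  # in-plane approaches
  for (i in seq_along(gaps_nm)) {
    cen <- ld_c + dirs[[i]] * (ld_r + gaps_nm[i] + r_m)
    mito[rasterize_sphere(dm, vs, cen, r_m)] <- i
  }
  list(mito = volume_grid(mito, vs), lds = volume_grid(lds, vs),
       nuc = volume_grid(nuc, vs))
}

test_that("planted surface gaps produce the expected contact flags", {
  sc <- planted_contact_scene(c(20, 40, 300))
  flags <- detect_contacts(sc$mito, sc$lds, sc$nuc,
                           contact_params(ld_contact_max = 50))
  expect_equal(flags$ld_contact, c(TRUE, TRUE, FALSE))
  # measured distances sit near the planted gaps (voxel quantization aside)
  expect_lt(max(abs(flags$ld_distance_nm - c(20, 40, 300))), 15)
})

test_that("classification follows the precedence and partitions the population", {
  flags <- data.frame(instance_id = 1:10,
                      nucleus_near = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)),
                      ld_contact = c(TRUE, TRUE, FALSE, FALSE, rep(FALSE, 6)))
  out <- classify_compartments(flags)
  expect_equal(out$labels$compartment,
               c("PDM", "PDM", "PNM", "PNM", rep("CM", 6)))
  expect_equal(unname(out$percentages), c(20, 20, 60))
  expect_equal(sum(out$percentages), 100, tolerance = 1e-9)
  # both flags false -> CM; both true -> PDM under the default precedence
  one <- classify_compartments(data.frame(instance_id = 1, nucleus_near = FALSE,
                                          ld_contact = FALSE))
  expect_equal(one$labels$compartment, "CM")
  both <- classify_compartments(data.frame(instance_id = 1, nucleus_near = TRUE,
                                           ld_contact = TRUE))
  expect_equal(both$labels$compartment, "PDM")
  # alternative precedence flips it
  alt <- classify_compartments(data.frame(instance_id = 1, nucleus_near = TRUE,
                                          ld_contact = TRUE),
                               contact_params(precedence = c("PNM", "PDM", "CM")))
  expect_equal(alt$labels$compartment, "PNM")
})

test_that("scenes without droplets have no PDM", {
  sc <- planted_contact_scene()
  empty <- sc$lds; empty$data[] <- 0L
  flags <- detect_contacts(sc$mito, empty, sc$nuc)
  expect_true(all(!flags$ld_contact))
  out <- classify_compartments(flags)
  expect_equal(unname(out$percentages["PDM"]), 0)
  expect_error(detect_contacts(sc$mito, sc$lds,
                               volume_grid(array(0L, dim(sc$nuc$data)),
                                           sc$nuc$voxel_size)),
               "nucleus")
})

test_that("PDM and PNM counts are monotone in their cutoffs", {
  sc <- planted_contact_scene(c(20, 40, 300))
  n_pdm <- vapply(c(10, 30, 60, 400), function(cut) {
    fl <- detect_contacts(sc$mito, sc$lds, sc$nuc,
                          contact_params(ld_contact_max = cut))
    sum(classify_compartments(fl)$labels$compartment == "PDM")
  }, numeric(1))
  expect_true(all(diff(n_pdm) >= 0))
  n_pn <- vapply(c(100, 1000, 4000), function(cut) {
    fl <- detect_contacts(sc$mito, sc$lds, sc$nuc,
                          contact_params(pnm_distance_max = cut))
    lab <- classify_compartments(fl)$labels$compartment
    sum(lab %in% c("PNM", "PDM"))
  }, numeric(1))
  expect_true(all(diff(n_pn) >= 0))
})

test_that("lipid droplet quantification matches planted spheres", {
  dm <- c(40, 200, 200); vs <- c(50, 5, 5)
  a <- array(0L, dm)
  r <- 150
  cents <- list(c(500, 250, 250), c(1500, 250, 750), c(800, 750, 500))
  for (i in seq_along(cents)) a[rasterize_sphere(dm, vs, cents[[i]], r)] <- i
  q <- quantify_lipid_droplets(volume_grid(a, vs))
  expect_equal(q$count, 3L)
  expect_lt(abs(q$total_volume_um3 / (3 * 4 / 3 * pi * 0.15^3) - 1), 0.05)
  # splitting one droplet label into two conserves total volume exactly
  b <- a
  w <- which(b == 1L)
  b[w[seq_len(length(w) %/% 2)]] <- 4L
  q2 <- quantify_lipid_droplets(volume_grid(b, vs))
  expect_equal(q2$count, 4L)
  expect_equal(q2$total_volume_um3, q$total_volume_um3)
  # no droplets
  q0 <- quantify_lipid_droplets(volume_grid(array(0L, c(4, 4, 4)), vs))
  expect_equal(q0$count, 0L)
  expect_equal(q0$total_volume_um3, 0)
})

test_that("tracer uptake phenotyping applies the inclusive thresholds", {
  tab <- data.frame(tracer = c("FBnTP", "FBnTP", "FBnTP", "FDG", "FDG", "FDG"),
                    tumour_uptake = c(0.50, 0.49, 0.80, 0.20, 0.19, 0.70),
                    heart_uptake = rep(1, 6))
  out <- classify_tracer_uptake(tab)
  expect_equal(out$phenotype, c("HI", "LO", "HI", "HI", "LO", "HI"))
  expect_equal(out$ratio, tab$tumour_uptake)
  expect_error(classify_tracer_uptake(data.frame(tracer = "FBnTP",
                                                 tumour_uptake = -1,
                                                 heart_uptake = 1)), "> 0")
  expect_error(classify_tracer_uptake(data.frame(tracer = "PET",
                                                 tumour_uptake = 1,
                                                 heart_uptake = 1)), "tracer")
})

test_that("respiratory capacity normalizes elementwise to mitochondrial content", {
  expect_equal(normalize_mrc(100, 2), 50)
  expect_equal(normalize_mrc(7.3, 1), 7.3)
  expect_equal(normalize_mrc(c(10, 20, 30), c(2, 4, 5)), c(5, 5, 6))
  expect_error(normalize_mrc(10, 0), "> 0")
})
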