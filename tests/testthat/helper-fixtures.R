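# Shared fixtures: everything is generated in code at test time.

# small, fast synthetic scene (fits the reduced grid)
small_scene_spec <- function(n_mito = 5, n_ld = 2, seed = 3, ...) {
  scene_spec(grid_shape = c(32, 288, 288),
             nucleus = list(semi_axes = c(350, 220, 220)),
             n_mitochondria = n_mito, n_lipid_droplets = n_ld,
             mito = list(length_mean_um = 0.3, length_sd_um = 0.05),
             ld = list(radius_mean = 100, radius_sd = 20),
             seed = seed, ...)
}

# 2D image/label pair with an ellipse "nucleus" and round "mitochondria",
# EM-like contrast; used for network overfit runs
make_seg_pair <- function(seed, side = 128) {
  set.seed(seed)
  lab <- matrix(0L, side, side)
  yy <- matrix(seq_len(side), side, side)
  xx <- t(yy)
  cy <- runif(1, side * 0.3, side * 0.7)
  cx <- runif(1, side * 0.3, side * 0.7)
  lab[((yy - cy) / (side * 0.17))^2 + ((xx - cx) / (side * 0.12))^2 <= 1] <- 1L
  for (b in 1:8) {
    by <- runif(1, 8, side - 8); bx <- runif(1, 8, side - 8)
    br <- runif(1, 3, 6)
    m <- (yy - by)^2 + (xx - bx)^2 <= br^2
    m[lab == 1L] <- FALSE
    lab[m] <- 2L
  }
  img <- c(0.8, 0.45, 0.2)[lab + 1L] + rnorm(side * side, 0, 0.05)
  list(image = matrix(img, side, side), label = lab)
}

# voxelized ball on an isotropic unit grid
make_ball <- function(r = 20) {
  n <- 2 * r + 11
  c0 <- (n + 1) / 2
  dm <- rep(n, 3)
  a <- array(0L, dm)
  a[rasterize_sphere(dm, c(1, 1, 1), rep((c0 - 1), 3), r)] <- 1L
  volume_grid(a, c(1, 1, 1))
}

# straight capsule volume at SBEM-like anisotropy
make_capsule <- function(len_nm = 2000, r_nm = 100, dirv = c(0, 0, 1),
                         vs = c(50, 5, 5)) {
  dirv <- dirv / sqrt(sum(dirv^2))
  half <- (len_nm / 2 + r_nm + 200)
  dmv <- ceiling(2 * half / vs) + 8
  cen <- (dmv - 1) * vs / 2
  pts <- rbind(cen - dirv * len_nm / 2, cen + dirv * len_nm / 2)
  a <- array(0L, dmv)
  a[rasterize_capsule(dmv, vs, pts, r_nm)] <- 1L
  volume_grid(a, vs)
}
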