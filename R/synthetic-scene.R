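#' Specification of a synthetic SBEM-like cell scene
#'
#' Describes a ground-truthed synthetic volume: an ellipsoidal nucleus,
#' capsule-shaped mitochondria whose axes are smoothed 3D random walks, and
#' spherical lipid droplets, rasterized on an anisotropic voxel grid and
#' rendered as EM-like grayscale (dark organelles, bright background and
#' brighter lipid) with additive Gaussian noise.
#'
#' The two `fragmentation` presets emulate the two network phenotypes seen in
#' lung tumour cells: `"elongated"` (long tubules, the high-OXPHOS
#' adenocarcinoma-like phenotype) and `"fragmented"` (short capsules, the
#' squamous-like phenotype).  `placement` controls the spatial prior:
#' `"perinuclear"` confines mitochondrion centroids to a shell of
#' `shell_width` nm outside the nucleus surface, `"dispersed"` spreads them
#' uniformly over the cytoplasm.
#'
#' @param grid_shape voxel counts `(nz, ny, nx)`.
#' @param voxel_size `(dz, dy, dx)` nm; the default matches SBEM sampling
#'   (50 nm section step, 5 nm pixels).
#' @param nucleus list with `semi_axes` (nm, `(z, y, x)`), `center` (nm,
#'   `(z, y, x)`; default grid centre) and `phi` (in-plane tilt, radians).
#' @param n_mitochondria,n_lipid_droplets instance counts, `>= 0`.
#' @param mito list: `radius` (tubule radius, nm), `length_mean_um` /
#'   `length_sd_um` (log-normal axis length distribution, um), `curvature`
#'   (per-step direction jitter of the axis walk; 0 gives straight capsules),
#'   `step_nm` (walk step).
#' @param fragmentation `"elongated"` or `"fragmented"`; presets for the
#'   length distribution, overridden by explicit `mito` values.
#' @param placement `"dispersed"` or `"perinuclear"`.
#' @param shell_width perinuclear shell width, nm.
#' @param ld list: `radius_mean`, `radius_sd` (nm).
#' @param pdm_fraction fraction of mitochondria planted in contact with a
#'   lipid droplet (surface gap sampled within the conventional 50 nm
#'   contact-site scale, approach direction in the imaging plane); ignored
#'   when there are no droplets.
#' @param intensity per-class grayscale means in `[0, 1]` plus `noise_sd`.
#' @param max_retries rejection-sampling cap per instance.
#' @param seed integer RNG seed; identical specs give bit-identical scenes.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(grid_shape = c(64, 512, 512),
                       voxel_size = c(50, 5, 5),
                       nucleus = list(),
                       n_mitochondria = 20,
                       mito = list(),
                       fragmentation = c("elongated", "fragmented"),
                       placement = c("dispersed", "perinuclear"),
                       shell_width = 1000,
                       n_lipid_droplets = 5,
                       ld = list(),
                       pdm_fraction = 0.25,
                       intensity = list(),
                       max_retries = 1000,
                       seed = 1) {
  fragmentation <- match.arg(fragmentation)
  placement <- match.arg(placement)
  grid_shape <- as.integer(grid_shape)
  voxel_size <- as.numeric(voxel_size)
  if (length(grid_shape) != 3L || any(grid_shape < 1)) stop("bad grid_shape")
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) stop("voxel sizes must be > 0")
  if (n_mitochondria < 0 || n_lipid_droplets < 0) stop("counts must be >= 0")
  if (shell_width <= 0) stop("shell_width must be > 0")

  extent <- (grid_shape - 1) * voxel_size
  nuc <- utils::modifyList(list(semi_axes = c(700, 550, 550),
                                center = extent / 2, phi = 0), nucleus)
  if (any(nuc$semi_axes <= 0)) stop("nucleus semi-axes must be > 0")
  rmax_xy <- max(nuc$semi_axes[2:3])
  lo <- nuc$center - c(nuc$semi_axes[1], rmax_xy, rmax_xy)
  hi <- nuc$center + c(nuc$semi_axes[1], rmax_xy, rmax_xy)
  if (any(lo < 0) || any(hi > extent)) stop("nucleus does not fit inside the grid")

  len_preset <- if (fragmentation == "elongated") c(1.2, 0.4) else c(0.4, 0.15)
  mito <- utils::modifyList(list(radius = 100,
                                 length_mean_um = len_preset[1],
                                 length_sd_um = len_preset[2],
                                 curvature = 0.25, step_nm = 100), mito)
  if (mito$radius <= 0 || mito$length_mean_um <= 0 || mito$length_sd_um < 0)
    stop("mitochondrion shape parameters must be positive")
  ld <- utils::modifyList(list(radius_mean = 150, radius_sd = 30), ld)
  if (ld$radius_mean <= 0 || ld$radius_sd < 0) stop("LD radius parameters must be positive")
  intensity <- utils::modifyList(list(background = 0.8, nucleus = 0.45,
                                      mitochondria = 0.2, lipid_droplet = 0.9,
                                      noise_sd = 0.05), intensity)

  structure(list(grid_shape = grid_shape, voxel_size = voxel_size, nucleus = nuc,
                 n_mitochondria = as.integer(n_mitochondria), mito = mito,
                 fragmentation = fragmentation, placement = placement,
                 shell_width = shell_width,
                 n_lipid_droplets = as.integer(n_lipid_droplets), ld = ld,
                 pdm_fraction = pdm_fraction,
                 intensity = intensity, max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# ---- rasterization helpers (physical coords in nm, (z, y, x) order) --------

# 1-based index range covering physical interval [lo, hi] on one axis
.vox_range <- function(lo, hi, n, d) {
  i0 <- max(1L, floor(lo / d) + 1L)
  i1 <- min(n, ceiling(hi / d) + 1L)
  if (i0 > i1) integer(0) else i0:i1
}

# voxel-centre coordinates of a crop as an N x 3 matrix (z, y, x), plus the
# linear indices of the crop voxels in the full array
.crop_coords <- function(iz, iy, ix, dim, voxel_size) {
  nz <- length(iz); ny <- length(iy); nx <- length(ix)
  zc <- (iz - 1) * voxel_size[1]
  yc <- (iy - 1) * voxel_size[2]
  xc <- (ix - 1) * voxel_size[3]
  co <- cbind(rep(zc, times = ny * nx),
              rep(rep(yc, each = nz), times = nx),
              rep(xc, each = nz * ny))
  lin <- rep(iz, times = ny * nx) +
    (rep(rep(iy, each = nz), times = nx) - 1L) * dim[1] +
    (rep(ix, each = nz * ny) - 1L) * dim[1] * dim[2]
  list(coords = co, lin = lin)
}

#' Rasterize an ellipsoid on a voxel grid
#'
#' @param dim grid shape `(nz, ny, nx)`.
#' @param voxel_size `(dz, dy, dx)` nm.
#' @param center,semi_axes physical nm, `(z, y, x)` order.
#' @param phi tilt of the ellipsoid in the x-y plane, radians.
#' @return integer vector of linear voxel indices inside the ellipsoid.
#' @export
rasterize_ellipsoid <- function(dim, voxel_size, center, semi_axes, phi = 0) {
  rxy <- max(semi_axes[2:3])
  iz <- .vox_range(center[1] - semi_axes[1], center[1] + semi_axes[1], dim[1], voxel_size[1])
  iy <- .vox_range(center[2] - rxy, center[2] + rxy, dim[2], voxel_size[2])
  ix <- .vox_range(center[3] - rxy, center[3] + rxy, dim[3], voxel_size[3])
  if (!length(iz) || !length(iy) || !length(ix)) return(integer(0))
  cc <- .crop_coords(iz, iy, ix, dim, voxel_size)
  dz <- cc$coords[, 1] - center[1]
  dy <- cc$coords[, 2] - center[2]
  dx <- cc$coords[, 3] - center[3]
  xr <- cos(phi) * dx + sin(phi) * dy
  yr <- -sin(phi) * dx + cos(phi) * dy
  q <- (dz / semi_axes[1])^2 + (yr / semi_axes[2])^2 + (xr / semi_axes[3])^2
  cc$lin[q <= 1]
}

#' Rasterize a sphere on a voxel grid
#' @inheritParams rasterize_ellipsoid
#' @param radius nm.
#' @return linear voxel indices.
#' @export
rasterize_sphere <- function(dim, voxel_size, center, radius) {
  rasterize_ellipsoid(dim, voxel_size, center, rep(radius, 3))
}

#' Rasterize a capsule (tube with hemispherical caps) along a polyline axis
#'
#' @inheritParams rasterize_ellipsoid
#' @param axis_points m x 3 matrix of physical points (nm, `(z, y, x)`) along
#'   the capsule axis.
#' @param radius tubule radius, nm.
#' @return linear voxel indices within `radius` of the axis polyline.
#' @export
rasterize_capsule <- function(dim, voxel_size, axis_points, radius) {
  axis_points <- rbind(axis_points)
  if (nrow(axis_points) == 1) axis_points <- axis_points[c(1, 1), , drop = FALSE]
  pad <- radius + max(voxel_size)
  hits <- vector("list", nrow(axis_points) - 1)
  for (s in seq_len(nrow(axis_points) - 1)) {
    a <- axis_points[s, ]; b <- axis_points[s + 1, ]
    lo <- pmin(a, b) - pad; hi <- pmax(a, b) + pad
    iz <- .vox_range(lo[1], hi[1], dim[1], voxel_size[1])
    iy <- .vox_range(lo[2], hi[2], dim[2], voxel_size[2])
    ix <- .vox_range(lo[3], hi[3], dim[3], voxel_size[3])
    if (!length(iz) || !length(iy) || !length(ix)) next
    cc <- .crop_coords(iz, iy, ix, dim, voxel_size)
    ab <- b - a
    ab2 <- sum(ab^2)
    if (ab2 == 0) {
      d2 <- (cc$coords[, 1] - a[1])^2 + (cc$coords[, 2] - a[2])^2 + (cc$coords[, 3] - a[3])^2
    } else {
      t <- ((cc$coords[, 1] - a[1]) * ab[1] + (cc$coords[, 2] - a[2]) * ab[2] +
              (cc$coords[, 3] - a[3]) * ab[3]) / ab2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (cc$coords[, 1] - (a[1] + t * ab[1]))^2 +
        (cc$coords[, 2] - (a[2] + t * ab[2]))^2 +
        (cc$coords[, 3] - (a[3] + t * ab[3]))^2
    }
    hits[[s]] <- cc$lin[d2 <= radius^2]
  }
  unique(unlist(hits))
}

# radius of the (tilted) nucleus ellipsoid along unit direction u from centre
.nucleus_radius_along <- function(nuc, u) {
  xr <- cos(nuc$phi) * u[3] + sin(nuc$phi) * u[2]
  yr <- -sin(nuc$phi) * u[3] + cos(nuc$phi) * u[2]
  1 / sqrt((u[1] / nuc$semi_axes[1])^2 + (yr / nuc$semi_axes[2])^2 +
             (xr / nuc$semi_axes[3])^2)
}

# signed radial distance from the nucleus surface (positive outside)
.nucleus_radial_distance <- function(nuc, p) {
  d <- p - nuc$center
  r <- sqrt(sum(d^2))
  if (r == 0) return(-min(nuc$semi_axes))
  r - .nucleus_radius_along(nuc, d / r)
}

# smoothed random-walk capsule axis of total length len starting at p0
.walk_axis <- function(p0, len, step, curvature) {
  nseg <- max(1L, ceiling(len / step))
  seg_len <- len / nseg
  pts <- matrix(0, nseg + 1, 3)
  pts[1, ] <- p0
  dir <- rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  for (s in seq_len(nseg)) {
    if (curvature > 0) {
      dir <- dir + curvature * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
    }
    pts[s + 1, ] <- pts[s, ] + dir * seg_len
  }
  pts
}

#' Generate a ground-truthed synthetic cell volume
#'
#' Rasterizes the scene described by a [scene_spec()]: nucleus first (always
#' instance 1), then mitochondria, then lipid droplets, each placed by
#' rejection sampling so that instances never overlap.  Grayscale is the
#' per-class mean plus i.i.d. Gaussian noise.  The same spec (including its
#' seed) always produces bit-identical output.
#'
#' @param spec a [scene_spec()].
#' @return list with `grayscale` (a [volume_grid()]), and `truth`: a list of
#'   `class_volume` (0 background, 1 nucleus, 2 mitochondria, 3 lipid
#'   droplet), `instance_volume` (dense positive ids, 0 = none) and
#'   `instance_table` (per-instance truth: class, centroid in um, exact
#'   voxel-count volume in um^3, capsule axis length in um, radius in nm).
#' @export
generate_cell_volume <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  dm <- spec$grid_shape
  vs <- spec$voxel_size
  extent <- (dm - 1) * vs
  n <- prod(dm)
  class_vol <- array(0L, dm)
  inst_vol <- array(0L, dm)

  nuc_idx <- rasterize_ellipsoid(dm, vs, spec$nucleus$center, spec$nucleus$semi_axes,
                                 spec$nucleus$phi)
  class_vol[nuc_idx] <- 1L
  inst_vol[nuc_idx] <- 1L
  next_id <- 2L

  meta <- list(list(instance_id = 1L, class = 1L, axis_length_um = NA_real_,
                    radius_nm = NA_real_, planted_pdm = FALSE))

  # lipid droplets first (mitochondria may be planted against them)
  ld_ids <- integer(0); ld_centers <- list(); ld_radii <- numeric(0)
  for (k in seq_len(spec$n_lipid_droplets)) {
    placed <- FALSE
    for (try in seq_len(spec$max_retries)) {
      rad <- max(2 * min(vs), rnorm(1, spec$ld$radius_mean, spec$ld$radius_sd))
      margin <- rad + max(vs)
      cen <- margin + runif(3) * (extent - 2 * margin)
      if (.nucleus_radial_distance(spec$nucleus, cen) < 0) next
      chk <- rasterize_sphere(dm, vs, cen, rad + 2.5 * max(vs))
      if (!length(chk) || any(class_vol[chk] != 0L)) next
      idx <- rasterize_sphere(dm, vs, cen, rad)
      if (!length(idx)) next
      class_vol[idx] <- 3L
      inst_vol[idx] <- next_id
      meta[[next_id]] <- list(instance_id = next_id, class = 3L,
                              axis_length_um = NA_real_, radius_nm = rad,
                              planted_pdm = FALSE)
      ld_ids <- c(ld_ids, next_id)
      ld_centers[[length(ld_ids)]] <- cen
      ld_radii <- c(ld_radii, rad)
      next_id <- next_id + 1L
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("failed to place lipid droplet %d after %d retries: scene too crowded",
                   k, spec$max_retries))
  }

  # log-normal parameters from arithmetic mean/sd (um)
  m <- spec$mito$length_mean_um; s <- spec$mito$length_sd_um
  sdlog <- sqrt(log1p((s / m)^2))
  meanlog <- log(m) - sdlog^2 / 2

  r <- spec$mito$radius
  n_pdm <- if (length(ld_ids)) round(spec$pdm_fraction * spec$n_mitochondria) else 0L
  for (k in seq_len(spec$n_mitochondria)) {
    plant <- k <= n_pdm
    placed <- FALSE
    for (try in seq_len(spec$max_retries)) {
      len_nm <- 1000 * if (sdlog > 0) rlnorm(1, meanlog, sdlog) else m
      target_ld <- 0L
      if (plant) {
        j <- (k - 1L) %% length(ld_ids) + 1L
        target_ld <- ld_ids[j]
        # approach in the imaging plane, surface gap well inside the contact scale
        phi <- runif(1, 0, 2 * pi)
        u0 <- c(0, sin(phi), cos(phi))
        gap <- runif(1, 5, 35)
        p0 <- ld_centers[[j]] + u0 * (ld_radii[j] + r + gap + 150)
        pts <- .walk_axis(p0, len_nm, spec$mito$step_nm, spec$mito$curvature)
        # translate the axis so its closest approach realizes the gap
        for (it in 1:3) {
          dc <- sqrt(rowSums(sweep(pts, 2, ld_centers[[j]])^2))
          i0 <- which.min(dc)
          u <- (pts[i0, ] - ld_centers[[j]]) / dc[i0]
          pts <- sweep(pts, 2, u * ((ld_radii[j] + r + gap) - dc[i0]), `+`)
        }
        dc <- sqrt(rowSums(sweep(pts, 2, ld_centers[[j]])^2))
        i0 <- which.min(dc)
        g <- dc[i0] - ld_radii[j] - r
        u <- (pts[i0, ] - ld_centers[[j]]) / dc[i0]
        if (g < 5 || g > 45 || abs(u[1]) > 0.5) next
      } else {
        p0 <- .sample_start(spec, extent, r)
        if (is.null(p0)) next
        pts <- .walk_axis(p0, len_nm, spec$mito$step_nm, spec$mito$curvature)
      }
      margin <- r + max(vs)
      if (any(pts < margin) || any(t(pts) > extent - margin)) next
      cen <- colMeans(pts)
      rd <- .nucleus_radial_distance(spec$nucleus, cen)
      if (rd < 0) next
      if (!plant && spec$placement == "perinuclear" && rd > spec$shell_width) next
      # clearance check with a dilated capsule so instances never touch
      # (the planted target droplet is exempt from the clearance, not from
      # the strict no-overlap check)
      chk <- rasterize_capsule(dm, vs, pts, r + 2.5 * max(vs))
      if (!length(chk)) next
      occ <- class_vol[chk] != 0L
      if (plant) occ <- occ & inst_vol[chk] != target_ld
      if (any(occ)) next
      idx <- rasterize_capsule(dm, vs, pts, r)
      if (!length(idx) || any(class_vol[idx] != 0L)) next
      class_vol[idx] <- 2L
      inst_vol[idx] <- next_id
      meta[[next_id]] <- list(instance_id = next_id, class = 2L,
                              axis_length_um = len_nm / 1000, radius_nm = r,
                              planted_pdm = plant)
      next_id <- next_id + 1L
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("failed to place mitochondrion %d after %d retries: scene too crowded",
                   k, spec$max_retries))
  }

  # per-instance centroids and exact voxel-count volumes
  fg <- which(inst_vol > 0L)
  ids <- inst_vol[fg]
  ai <- arrayInd(fg, dm)
  vc <- tabulate(ids, nbins = next_id - 1L)
  idf <- factor(ids, levels = seq_len(next_id - 1L))
  cz <- tapply((ai[, 1] - 1) * vs[1], idf, mean) / 1000
  cy <- tapply((ai[, 2] - 1) * vs[2], idf, mean) / 1000
  cx <- tapply((ai[, 3] - 1) * vs[3], idf, mean) / 1000
  tab <- data.frame(
    instance_id = seq_len(next_id - 1L),
    class = vapply(meta, function(m) m$class, integer(1)),
    voxel_count = vc,
    volume_um3 = vc * voxel_volume_um3(vs),
    centroid_z_um = as.numeric(cz),
    centroid_y_um = as.numeric(cy),
    centroid_x_um = as.numeric(cx),
    axis_length_um = vapply(meta, function(m) m$axis_length_um, numeric(1)),
    radius_nm = vapply(meta, function(m) m$radius_nm, numeric(1)),
    planted_pdm = vapply(meta, function(m) m$planted_pdm, logical(1))
  )

  means <- c(spec$intensity$background, spec$intensity$nucleus,
             spec$intensity$mitochondria, spec$intensity$lipid_droplet)
  gray <- array(means[class_vol + 1L] + rnorm(n, 0, spec$intensity$noise_sd), dm)

  list(grayscale = volume_grid(gray, vs),
       truth = list(class_volume = volume_grid(class_vol, vs),
                    instance_volume = volume_grid(inst_vol, vs),
                    instance_table = tab))
}

.sample_start <- function(spec, extent, r) {
  nuc <- spec$nucleus
  margin <- r + max(spec$voxel_size)
  if (spec$placement == "perinuclear") {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    rad <- .nucleus_radius_along(nuc, u) + runif(1, 0, spec$shell_width)
    pmin(pmax(nuc$center + u * rad, margin), extent - margin)
  } else {
    for (i in 1:100) {
      p <- margin + runif(3) * (extent - 2 * margin)
      if (.nucleus_radial_distance(nuc, p) > 0) return(p)
    }
    NULL   # counts as a failed attempt; the placement retry loop handles it
  }
}

#' Sample points exactly on an ellipse boundary
#'
#' Parametric sampling `(a cos t, b sin t)` followed by the rigid transform of
#' the ellipse.  With `random = FALSE` (default) the parameter angles are
#' evenly spaced starting at 0, so `n = 4` on an axis-aligned ellipse gives
#' exactly `(a, 0), (0, b), (-a, 0), (0, -b)`.
#'
#' @param e an [ellipse_shape()].
#' @param n number of points, `>= 1`.
#' @param random sample angles uniformly at random instead.
#' @param seed optional seed used when `random = TRUE`.
#' @return n x 2 matrix of (x, y) points on the ellipse.
#' @export
sample_ellipse_boundary <- function(e, n, random = FALSE, seed = NULL) {
  stopifnot(inherits(e, "ellipse_shape"), n >= 1)
  if (random) {
    if (!is.null(seed)) set.seed(seed)
    t <- runif(n, 0, 2 * pi)
  } else {
    t <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  }
  xs <- e$a * cos(t)
  ys <- e$b * sin(t)
  xr <- cos(e$theta) * xs - sin(e$theta) * ys + e$center[1]
  yr <- sin(e$theta) * xs + cos(e$theta) * ys + e$center[2]
  cbind(x = xr, y = yr)
}
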