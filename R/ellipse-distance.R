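#' Ellipse in physical coordinates
#'
#' The fitted 2D nucleus boundary: centre, semi-major axis `a`, semi-minor
#' axis `b` and tilt `theta` (angle of the major axis against +x, normalized
#' to `[0, pi)`).
#'
#' @param center numeric length 2 `(cx, cy)`.
#' @param a,b semi-axes, `a >= b > 0`.
#' @param theta tilt in radians.
#' @return object of class `ellipse_shape`.
#' @export
ellipse_shape <- function(center, a, b, theta = 0) {
  if (!(b > 0) || !(a >= b)) stop("require a >= b > 0")
  theta <- theta %% pi
  structure(list(center = as.numeric(center), a = a, b = b, theta = theta),
            class = "ellipse_shape")
}

#' Fit the nucleus boundary as a moment-equivalent ellipse
#'
#' Centre from the mask centroid; axes and tilt from the eigendecomposition
#' of the second-order central moments (semi-axis = 2 sqrt(eigenvalue), the
#' moment-equivalent solid ellipse).  Pixel centres are at 0-based integer
#' coordinates, rows = y, columns = x.
#'
#' @param mask 2D binary matrix.
#' @return an [ellipse_shape()].
#' @export
fit_nucleus_ellipse <- function(mask) {
  px <- which(mask > 0, arr.ind = TRUE)
  if (nrow(px) == 0) stop("empty mask")
  y <- px[, 1] - 1
  x <- px[, 2] - 1
  cx <- mean(x); cy <- mean(y)
  cxx <- mean((x - cx)^2); cyy <- mean((y - cy)^2); cxy <- mean((x - cx) * (y - cy))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  if (ev$values[2] <= .Machine$double.eps * max(1, ev$values[1]))
    stop("degenerate (collinear) mask: cannot fit an ellipse")
  a <- 2 * sqrt(ev$values[1])
  b <- 2 * sqrt(ev$values[2])
  v <- ev$vectors[, 1]             # (x, y) components of the major axis
  ellipse_shape(c(cx, cy), a, b, atan2(v[2], v[1]))
}

# squared distance from (u, v) to the parametric point t, and Newton polish
.polish_param <- function(t, a, b, u, v, iters = 6) {
  for (i in seq_len(iters)) {
    ct <- cos(t); st <- sin(t)
    g1 <- -(a * ct - u) * a * st + (b * st - v) * b * ct
    g2 <- -(a * ct - u) * a * ct + a^2 * st^2 + (b * st - v) * b * (-st) + b^2 * ct^2
    if (!is.finite(g2) || abs(g2) < 1e-300) break
    step <- g1 / g2
    step <- max(min(step, 0.5), -0.5)   # safeguard
    t <- t - step
    if (abs(step) < 1e-15) break
  }
  t
}

#' Minimum distance from a point to an ellipse
#'
#' Solves the constrained minimization with Lagrange multipliers: the point
#' and ellipse are rigidly transformed to the standard frame (ellipse centred
#' at the origin, axes aligned), where stationarity reduces to a fourth-degree
#' polynomial in the boundary ordinate y with at most four real roots.  Roots
#' are found as eigenvalues of the companion matrix, each root's abscissa is
#' recovered from the stationarity relation `x = u a^2 y / ((a^2 - b^2) y +
#' b^2 v)` (so the general-position branch examines at most 4 candidates),
#' and the best candidate is polished on the parametric form before mapping
#' back.  Points exactly at the centre or on an axis are handled by the
#' analytic degenerate branches.
#'
#' @param p numeric length 2, the query point (e.g. a mitochondrion centroid).
#' @param e an [ellipse_shape()].
#' @return list of class `ellipse_distance`: `distance` (>= 0),
#'   `closest_point` (x, y on the ellipse, original frame), `n_candidates`
#'   (stationary candidates examined, <= 4 in general position).
#' @export
point_to_ellipse_distance <- function(p, e) {
  stopifnot(inherits(e, "ellipse_shape"), length(p) == 2, all(is.finite(p)))
  a <- e$a; b <- e$b
  # to standard frame
  d <- as.numeric(p) - e$center
  u <- cos(e$theta) * d[1] + sin(e$theta) * d[2]
  v <- -sin(e$theta) * d[1] + cos(e$theta) * d[2]

  tiny <- 1e-12 * a
  cands <- NULL                        # parameter angles of candidates
  if (abs(a - b) <= 1e-14 * a) {
    # circle: radial closed form
    r <- sqrt(u^2 + v^2)
    t0 <- if (r < tiny) pi / 2 else atan2(v, u)
    cands <- t0
  } else if (abs(u) <= tiny && abs(v) <= tiny) {
    # centre: nearest point is on the minor axis (tie broken toward +y)
    cands <- pi / 2
  } else if (abs(v) <= tiny) {
    # on the major axis: vertices plus (inside the evolute) off-axis points
    c2 <- a^2 - b^2
    cands <- c(0, pi)
    if (abs(u) < c2 / a) {
      x0 <- a^2 * u / c2
      y0 <- b * sqrt(max(0, 1 - x0^2 / a^2))
      cands <- c(cands, atan2(y0 / b, x0 / a), atan2(-y0 / b, x0 / a))
    }
  } else if (abs(u) <= tiny) {
    # on the minor axis
    c2 <- a^2 - b^2
    cands <- c(pi / 2, -pi / 2)
    if (abs(v) < c2 / b) {
      y0 <- -b^2 * v / (b^2 - a^2)   # = b^2 v / c2
      x0 <- a * sqrt(max(0, 1 - y0^2 / b^2))
      cands <- c(cands, atan2(y0 / b, x0 / a), atan2(y0 / b, -x0 / a))
    }
  } else {
    # general position: quartic in y
    cc <- a^2 - b^2
    k4 <- cc^2
    k3 <- 2 * cc * b^2 * v
    k2 <- b^4 * v^2 - b^2 * cc^2 + u^2 * a^2 * b^2
    k1 <- -2 * cc * b^4 * v
    k0 <- -b^6 * v^2
    comp <- rbind(c(-k3, -k2, -k1, -k0) / k4, diag(1, 3, 4))
    ev <- eigen(comp, only.values = TRUE)$values
    keep <- abs(Im(ev)) <= 1e-9 * pmax(1, abs(ev))
    yr <- Re(ev[keep])
    yr <- pmin(pmax(yr, -b), b)
    D <- cc * yr + b^2 * v
    xs <- ifelse(abs(D) > 1e-300, u * a^2 * yr / D,
                 a * sqrt(pmax(0, 1 - yr^2 / b^2)) * sign(u))
    cands <- atan2(yr / b, xs / a)
  }

  n_candidates <- length(cands)
  ct <- cos(cands); st <- sin(cands)
  d2 <- (a * ct - u)^2 + (b * st - v)^2
  tbest <- cands[which.min(d2)]
  tbest <- .polish_param(tbest, a, b, u, v)
  qx <- a * cos(tbest); qy <- b * sin(tbest)
  dist <- sqrt((qx - u)^2 + (qy - v)^2)
  # back to the original frame
  cx <- cos(e$theta) * qx - sin(e$theta) * qy + e$center[1]
  cy <- sin(e$theta) * qx + cos(e$theta) * qy + e$center[2]
  structure(list(distance = dist, closest_point = c(x = cx, y = cy),
                 n_candidates = n_candidates),
            class = "ellipse_distance")
}

#' Dense-sampling distance oracle (reference implementation for testing)
#'
#' Brute-force minimum over a dense parametric sampling of the boundary,
#' followed by golden-section refinement in the best bracket.  Independent of
#' the quartic solver; used to validate it.
#'
#' @inheritParams point_to_ellipse_distance
#' @param n_samples initial boundary sampling density.
#' @return minimum distance (numeric scalar).
#' @export
point_to_ellipse_distance_oracle <- function(p, e, n_samples = 3600) {
  d <- as.numeric(p) - e$center
  u <- cos(e$theta) * d[1] + sin(e$theta) * d[2]
  v <- -sin(e$theta) * d[1] + cos(e$theta) * d[2]
  f <- function(t) (e$a * cos(t) - u)^2 + (e$b * sin(t) - v)^2
  ts <- seq(0, 2 * pi, length.out = n_samples + 1)[seq_len(n_samples)]
  i <- which.min(f(ts))
  lo <- ts[i] - 2 * pi / n_samples
  hi <- ts[i] + 2 * pi / n_samples
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-14)
  sqrt(max(0, opt$objective))
}

#' Per-mitochondrion 3D distance to the nucleus surface
#'
#' Anisotropy-aware Euclidean distance transform from the nucleus voxels;
#' per instance either the minimum over its voxels (`"surface"`, default) or
#' the value at its centroid voxel (`"centroid"`).  Instances inside the
#' nucleus footprint get distance 0.
#'
#' @param instances instance-labelled [volume_grid()].
#' @param nucleus_mask binary [volume_grid()] on the same grid.
#' @param mode `"surface"` or `"centroid"`.
#' @return data.frame with `instance_id` and `distance_um`.
#' @export
mito_nucleus_distances_3d <- function(instances, nucleus_mask,
                                      mode = c("surface", "centroid")) {
  mode <- match.arg(mode)
  instances <- as_volume_grid(instances)
  nucleus_mask <- as_volume_grid(nucleus_mask, instances)
  stopifnot_aligned(instances, nucleus_mask)
  nuc <- nucleus_mask$data > 0
  if (!any(nuc)) stop("empty nucleus mask")
  dm <- dim(instances$data)
  edt <- sqrt(edt_sq_cpp(as.logical(nuc), dm, instances$voxel_size))
  ids <- sort(unique(instances$data[instances$data > 0]))
  dist_nm <- vapply(ids, function(id) {
    w <- which(instances$data == id)
    if (mode == "surface") {
      min(edt[w])
    } else {
      ai <- arrayInd(w, dm)
      cen <- colMeans(ai)
      vi <- pmin(pmax(round(cen), 1), dm)
      edt[vi[1], vi[2], vi[3]]
    }
  }, numeric(1))
  data.frame(instance_id = as.integer(ids), distance_um = dist_nm / 1000)
}
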