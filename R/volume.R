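#' 3D scalar field with anisotropic physical voxel size
#'
#' The substrate for raw images and label volumes.  Data are indexed
#' `(z, y, x)`; `voxel_size` is `(dz, dy, dx)` in nanometres.  The physical
#' coordinate of the centre of 0-based voxel `(k, j, i)` is
#' `origin + (k * dz, j * dy, i * dx)`.
#'
#' @param data 3D numeric, integer or logical array, dim `(nz, ny, nx)`.
#' @param voxel_size numeric length 3, `(dz, dy, dx)` in nm, all `> 0`.
#'   SBEM sampling is typically strongly anisotropic (50 nm section steps vs
#'   5 nm pixels), so the default is `c(50, 5, 5)`.
#' @param origin physical offset in nm, length 3 `(z, y, x)`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_size = c(50, 5, 5), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be 3 strictly positive numbers (dz, dy, dx) in nm")
  if (length(origin) != 3L) stop("`origin` must have length 3")
  structure(list(data = data, voxel_size = voxel_size, origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels (z,y,x), voxel %g x %g x %g nm, %s\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              typeof(x$data)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

#' Physical voxel volume in cubic micrometres
#' @param x a `volume_grid` or a numeric voxel-size triple in nm.
#' @return scalar, um^3 per voxel.
#' @export
voxel_volume_um3 <- function(x) {
  vs <- if (inherits(x, "volume_grid")) x$voxel_size else as.numeric(x)
  prod(vs) * 1e-9
}

as_volume_grid <- function(x, template = NULL) {
  if (inherits(x, "volume_grid")) return(x)
  if (!is.null(template))
    return(volume_grid(x, voxel_size = template$voxel_size, origin = template$origin))
  volume_grid(x)
}

stopifnot_aligned <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes have different grid shapes")
  if (max(abs(a$voxel_size - b$voxel_size)) > 1e-9)
    stop("volumes have different voxel sizes")
  invisible(TRUE)
}
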