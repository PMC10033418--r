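#' Write a volume as multi-page TIFF (with a voxel-size sidecar)
#'
#' Grayscale volumes are stored as 32-bit float pages; integer label volumes
#' as 16-bit pages.  TIFF tags are not trusted for section spacing, so the
#' voxel size travels in a small YAML sidecar (`<path>.meta.yaml`) that
#' [read_volume()] picks up automatically.
#'
#' @param volume a [volume_grid()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "volume_grid"))
  v <- volume$data
  is_label <- is.integer(v) || is.logical(v) ||
    (is.numeric(v) && all(v == round(v)) && max(v) < 65536 && min(v) >= 0)
  pages <- lapply(seq_len(dim(v)[1]), function(k) {
    if (is_label) matrix(as.numeric(v[k, , ]) / 65535, dim(v)[2], dim(v)[3])
    else matrix(as.numeric(v[k, , ]), dim(v)[2], dim(v)[3])
  })
  # 32 bits per sample stores IEEE float pages (values outside [0,1], e.g.
  # noise tails, survive the round trip); 16 bits stores integers
  suppressWarnings(
    tiff::writeTIFF(pages, path, bits.per.sample = if (is_label) 16L else 32L,
                    compression = "deflate"))
  yaml::write_yaml(list(voxel_size = as.numeric(volume$voxel_size),
                        origin = as.numeric(volume$origin),
                        kind = if (is_label) "label" else "gray"),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a volume from multi-page TIFF or MRC
#'
#' Returns a `(z, y, x)` array wrapped in a [volume_grid()].  The voxel size
#' comes from the sidecar written by [write_volume()], from the MRC cell
#' header, or from the `voxel_size` argument; TIFF tags are never trusted
#' for the section spacing.
#'
#' @param path file path; format inferred from the extension (`.tif/.tiff`
#'   or `.mrc/.rec/.st`) unless given.
#' @param format `"tiff"`, `"mrc"` or `NULL` (auto).
#' @param voxel_size fallback `(dz, dy, dx)` nm when no metadata is found.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path, format = NULL, voxel_size = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tif = , tiff = "tiff", mrc = , rec = , st = "mrc",
                     stop("unknown volume format: .", ext))
  }
  if (format == "mrc") return(read_mrc(path, voxel_size = voxel_size))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  for (p in pages) if (!identical(dim(p), d2)) stop("inconsistent page shapes in ", path)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else NULL
  arr <- array(0, c(length(pages), d2[1], d2[2]))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  if (!is.null(meta) && identical(meta$kind, "label")) {
    arr <- array(as.integer(round(arr * 65535)), dim(arr))
  }
  vs <- meta$voxel_size %||% voxel_size %||% c(1, 1, 1)
  org <- meta$origin %||% c(0, 0, 0)
  volume_grid(arr, vs, org)
}

#' Read an MRC volume (read-only, little-endian, modes 0/1/2/6)
#'
#' Minimal parser for the standard 1024-byte MRC2014 header: dimensions
#' `(nx, ny, nz)`, data mode, extended-header length, and the unit cell for
#' the voxel size (Angstrom -> nm).  Data are returned in `(z, y, x)` order.
#'
#' @param path MRC file.
#' @param voxel_size fallback voxel size in nm when the cell header is zero.
#' @return a [volume_grid()].
#' @export
read_mrc <- function(path, voxel_size = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  seek(con, 40)
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 92)
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  seek(con, 1024 + nsymbt)
  n <- nx * ny * nz
  data <- switch(as.character(mode),
                 "0" = readBin(con, "integer", n, size = 1, signed = TRUE, endian = "little"),
                 "1" = readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little"),
                 "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
                 "6" = readBin(con, "integer", n, size = 2, signed = FALSE, endian = "little"),
                 stop("unsupported MRC mode: ", mode))
  if (length(data) < n) stop("truncated MRC data in ", path)
  arr <- aperm(array(data, c(nx, ny, nz)), c(3, 2, 1))
  vs <- if (all(cella > 0)) rev(cella / c(nx, ny, nz)) * 0.1 else voxel_size %||% c(1, 1, 1)
  volume_grid(arr, vs)
}

#' Write a data.frame as CSV with unit documentation in a comment header
#' @param df data.frame.
#' @param path output path.
#' @param comment optional single comment line (units, provenance).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
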