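# Discretization of a filled phantom into a voxel grid carrying the local
# fiber orientation: a voxel is tissue when its center lies inside some
# fiber capsule (distance to the nearest axis segment below that fiber's
# local radius); ties go to the nearest axis.

#' Voxelize a filled phantom
#'
#' @param phantom A filled `fiber_phantom` (leaf fibers with radii).
#' @param bbox Bounding box: a 2 x 3 matrix `rbind(min, max)` or a length-6
#'   vector `c(xmin, xmax, ymin, ymax, zmin, zmax)`, micrometres.
#' @param voxel_size Voxel edge length, micrometres (default 1).
#' @return A `voxel_volume`: list with `dim` (3 integers), `origin` (corner
#'   of the first voxel), `voxel_size`, `orientation` (array
#'   `dim x 3` of unit vectors, NA outside tissue), `tissue` (logical array),
#'   and `dist` (distance to the winning axis, Inf outside).
#' @examples
#' fb <- fiber_points(c(-10, 10), c(0, 0), c(0, 0), c(2, 2), "f")
#' vol <- voxelize(fb, c(-5, 5, -4, 4, -4, 4), 1)
#' sum(vol$tissue)
#' @export
voxelize <- function(phantom, bbox, voxel_size = 1) {
  phantom <- as_fiber_phantom(phantom)
  if (!is.numeric(voxel_size) || voxel_size <= 0) {
    stop_validation("voxel_size must be > 0")
  }
  if (is.matrix(bbox)) {
    lo <- bbox[1, ]; hi <- bbox[2, ]
  } else if (length(bbox) == 6) {
    lo <- bbox[c(1, 3, 5)]; hi <- bbox[c(2, 4, 6)]
  } else {
    stop_validation("bbox must be a 2x3 matrix or a length-6 vector")
  }
  if (any(!is.finite(c(lo, hi))) || any(hi <= lo)) {
    stop_validation("bbox must be finite with max > min on every axis")
  }
  dims <- pmax(1L, as.integer(round((hi - lo) / voxel_size)))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  best <- array(Inf, dims)
  orient <- array(NA_real_, c(dims, 3))
  seg <- phantom_segments(phantom)
  # drop segments that cannot reach the box
  rmax_all <- max(seg$ra, seg$rb)
  inbox <- !(pmax(seg$ax, seg$bx) < lo[1] - rmax_all |
               pmin(seg$ax, seg$bx) > hi[1] + rmax_all |
               pmax(seg$ay, seg$by) < lo[2] - rmax_all |
               pmin(seg$ay, seg$by) > hi[2] + rmax_all |
               pmax(seg$az, seg$bz) < lo[3] - rmax_all |
               pmin(seg$az, seg$bz) > hi[3] + rmax_all)
  seg <- seg[inbox, ]
  ctr <- function(k, n) lo[k] + (seq_len(n) - 0.5) * voxel_size
  cx <- ctr(1, nx); cy <- ctr(2, ny); cz <- ctr(3, nz)
  rng <- function(a, b, r, centers) {
    which(centers >= min(a, b) - r & centers <= max(a, b) + r)
  }
  for (s in seq_len(nrow(seg))) {
    a <- c(seg$ax[s], seg$ay[s], seg$az[s])
    b <- c(seg$bx[s], seg$by[s], seg$bz[s])
    rmax <- max(seg$ra[s], seg$rb[s])
    ix <- rng(a[1], b[1], rmax, cx)
    iy <- rng(a[2], b[2], rmax, cy)
    iz <- rng(a[3], b[3], rmax, cz)
    if (!length(ix) || !length(iy) || !length(iz)) next
    g <- expand.grid(ix = ix, iy = iy, iz = iz)
    px <- cx[g$ix]; py <- cy[g$iy]; pz <- cz[g$iz]
    d <- b - a
    len2 <- sum(d^2)
    tpar <- pmin(1, pmax(0, ((px - a[1]) * d[1] + (py - a[2]) * d[2] +
                               (pz - a[3]) * d[3]) / len2))
    qx <- a[1] + tpar * d[1]; qy <- a[2] + tpar * d[2]; qz <- a[3] + tpar * d[3]
    dist <- sqrt((px - qx)^2 + (py - qy)^2 + (pz - qz)^2)
    rloc <- seg$ra[s] + tpar * (seg$rb[s] - seg$ra[s])
    lin <- g$ix + nx * (g$iy - 1L) + nx * ny * (g$iz - 1L)
    win <- dist < rloc & dist < best[lin]
    if (!any(win)) next
    lin <- lin[win]
    best[lin] <- dist[win]
    u <- d / sqrt(len2)
    nvox <- length(best)
    orient[lin] <- u[1]
    orient[lin + nvox] <- u[2]
    orient[lin + 2 * nvox] <- u[3]
  }
  structure(
    list(
      dim = dims, origin = lo, voxel_size = voxel_size,
      orientation = orient, tissue = is.finite(best), dist = best
    ),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf(
    "# voxel volume: %d x %d x %d voxels of %g um, %.1f%% tissue\n",
    x$dim[1], x$dim[2], x$dim[3], x$voxel_size,
    100 * mean(x$tissue)
  ))
  invisible(x)
}

#' Write / read a voxel volume as an HDF5 dataset
#'
#' Stores the orientation field (`dim x 3`, NaN outside tissue) with grid
#' metadata attributes, for exchange with the simulation stage.
#'
#' @param volume A `voxel_volume`.
#' @param path File path.
#' @return `path` invisibly; `read_voxel_volume()` returns a `voxel_volume`.
#' @export
write_voxel_volume <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stop_io(paste0("cannot create HDF5 file: ", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(volume$orientation, path, "orientation")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(.h5_format_version, fid, "format_version")
  rhdf5::h5writeAttribute("um", fid, "units")
  rhdf5::h5writeAttribute(as.numeric(volume$origin), fid, "origin")
  rhdf5::h5writeAttribute(volume$voxel_size, fid, "voxel_size")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_voxel_volume
#' @export
read_voxel_volume <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  orient <- rhdf5::h5read(path, "orientation")
  attrs <- rhdf5::h5readAttributes(path, "/")
  tissue <- is.finite(orient[, , , 1, drop = FALSE])
  dim(tissue) <- dim(orient)[1:3]
  orient[is.nan(orient)] <- NA_real_
  structure(
    list(
      dim = dim(orient)[1:3],
      origin = as.numeric(attrs$origin),
      voxel_size = as.numeric(attrs$voxel_size),
      orientation = orient, tissue = tissue,
      dist = array(ifelse(tissue, 0, Inf), dim(orient)[1:3])
    ),
    class = "voxel_volume"
  )
}
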