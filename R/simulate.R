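# Mueller-matrix forward simulation of a 3D-PLI measurement. A Stokes vector
# per image column passes a rotating linear polarizer, the voxelized tissue
# (one linear retarder per voxel, fast axis along the in-plane fiber
# direction, plus absorption), a quarter-wave retarder and a crossed
# analyzer. For a homogeneous column this chain reduces to the closed form
#   I(rho) = (I_T / 2) * (1 + sin(2 rho - 2 phi) * sin(delta_total)).

#' Optical and acquisition parameters for the 3D-PLI simulation
#'
#' Defaults follow a standard transmission polarimeter for unstained brain
#' sections: wavelength 525 nm, birefringence strength 0.001, absorption
#' 5 / mm, ingoing (polarized) intensity 26,000 counts, section thickness
#' 60 um, 9 polarizer angles 0..160 degrees in 20 degree steps, camera pixel
#' size 20 um, Gaussian blur sigma = 0.714 * pixel_size.
#'
#' @param wavelength Light wavelength, nm.
#' @param birefringence Birefringence strength `dn` (dimensionless).
#' @param absorption Intensity attenuation coefficient, 1/mm (tissue only).
#' @param I0 Intensity of the polarized beam entering the specimen, counts.
#' @param thickness Section thickness, um.
#' @param angles Polarizer rotation angles, radians; at least 3, equally
#'   spaced over `[0, pi)`.
#' @param pixel_size Camera pixel edge, um (integer multiple of the voxel size).
#' @param blur_factor Gaussian sigma as a fraction of `pixel_size`.
#' @param noise_gain Variance-to-intensity ratio of the sensor noise
#'   (Gaussian shot-noise approximation); the default gives SNR of about 100
#'   at intensity `I0 / 2`.
#' @param noise Logical: apply noise in [add_noise()]?
#' @return An `optics_params` list.
#' @export
optics_params <- function(wavelength = 525, birefringence = 0.001,
                          absorption = 5, I0 = 26000, thickness = 60,
                          angles = seq(0, 160, by = 20) * pi / 180,
                          pixel_size = 20, blur_factor = 0.714,
                          noise_gain = I0 / 2 / 100^2, noise = TRUE) {
  if (any(c(wavelength, I0, pixel_size, thickness) <= 0)) {
    stop_validation("wavelength, I0, pixel_size and thickness must be > 0")
  }
  if (length(unique(angles)) < 3) {
    stop_validation("at least 3 distinct polarizer angles are required")
  }
  structure(
    list(
      wavelength = wavelength, birefringence = birefringence,
      absorption = absorption, I0 = I0, thickness = thickness,
      angles = angles, pixel_size = pixel_size, blur_factor = blur_factor,
      noise_gain = noise_gain, noise = noise
    ),
    class = "optics_params"
  )
}

# dimension-safe component / layer extraction (singleton axes must survive)
orient_comp <- function(volume, k) {
  a <- volume$orientation[, , , k, drop = FALSE]
  dim(a) <- volume$dim
  a
}

vol_layer <- function(a, dims, iz) {
  m <- a[, , iz, drop = FALSE]
  dim(m) <- dims[1:2]
  m
}

# retardance of one voxel: delta = 2 pi (voxel_size / lambda) dn cos^2(alpha),
# with cos^2(alpha) = ox^2 + oy^2 for a unit orientation (ox, oy, oz)
voxel_retardance <- function(volume, params) {
  lam_um <- params$wavelength / 1000
  cos2a <- orient_comp(volume, 1)^2 + orient_comp(volume, 2)^2
  cos2a[is.na(cos2a)] <- 0
  2 * pi * (volume$voxel_size / lam_um) * params$birefringence * cos2a
}

#' Simulate the polarimetric image series of a voxel volume
#'
#' Propagates one Stokes vector per (x, y) column through the volume for
#' each polarizer angle and returns the detected intensity images at voxel
#' resolution.
#'
#' @param volume A `voxel_volume` from [voxelize()].
#' @param params An `optics_params` list.
#' @param check_stokes Assert the physicality bound
#'   `S0 >= |(S1, S2, S3)|` after every propagation step.
#' @return A `pli_stack`: numeric array `nx x ny x n_angles` with attributes
#'   `angles`, `pixel_size` and `params`.
#' @export
simulate_measurement <- function(volume, params = optics_params(),
                                 check_stokes = FALSE) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!inherits(params, "optics_params")) {
    stop_validation("params must come from optics_params()")
  }
  if (params$thickness <= 0) stop_validation("thickness must be > 0")
  nx <- volume$dim[1]; ny <- volume$dim[2]; nz <- volume$dim[3]
  delta <- voxel_retardance(volume, params)
  phi_vox <- atan2(orient_comp(volume, 2), orient_comp(volume, 1))
  phi_vox[is.na(phi_vox)] <- 0
  tissue <- volume$tissue
  dim(tissue) <- volume$dim
  # intensity attenuation per tissue voxel (absorption in 1/mm, sizes in um)
  att <- exp(-params$absorption * volume$voxel_size / 1000)
  out <- array(NA_real_, c(nx, ny, length(params$angles)))
  for (k in seq_along(params$angles)) {
    rho <- params$angles[k]
    S0 <- matrix(params$I0, nx, ny)
    S1 <- S0 * cos(2 * rho)
    S2 <- S0 * sin(2 * rho)
    S3 <- matrix(0, nx, ny)
    for (iz in seq_len(nz)) {
      th <- vol_layer(phi_vox, volume$dim, iz)
      dl <- vol_layer(delta, volume$dim, iz)
      c2 <- cos(2 * th); s2 <- sin(2 * th)
      cd <- cos(dl); sd <- sin(dl)
      # linear retarder, fast axis th, retardance dl
      n1 <- (c2^2 + s2^2 * cd) * S1 + c2 * s2 * (1 - cd) * S2 - s2 * sd * S3
      n2 <- c2 * s2 * (1 - cd) * S1 + (s2^2 + c2^2 * cd) * S2 + c2 * sd * S3
      n3 <- s2 * sd * S1 - c2 * sd * S2 + cd * S3
      S1 <- n1; S2 <- n2; S3 <- n3
      a <- ifelse(vol_layer(tissue, volume$dim, iz), att, 1)
      S0 <- S0 * a; S1 <- S1 * a; S2 <- S2 * a; S3 <- S3 * a
      if (check_stokes) {
        slack <- S0 * (1 + 1e-9) - sqrt(S1^2 + S2^2 + S3^2)
        if (any(slack < -1e-9 * params$I0)) {
          abort("unphysical Stokes vector during propagation")
        }
      }
    }
    # quarter-wave retarder, fast axis rho - pi/4
    th <- rho - pi / 4
    c2 <- cos(2 * th); s2 <- sin(2 * th)
    n1 <- c2^2 * S1 + c2 * s2 * S2 - s2 * S3
    n2 <- c2 * s2 * S1 + s2^2 * S2 + c2 * S3
    n3 <- s2 * S1 - c2 * S2
    S1 <- n1; S2 <- n2; S3 <- n3
    # analyzer: linear polarizer crossed at rho + pi/2
    ca <- cos(2 * (rho + pi / 2)); sa <- sin(2 * (rho + pi / 2))
    out[, , k] <- 0.5 * (S0 + ca * S1 + sa * S2)
  }
  structure(out, angles = params$angles, pixel_size = volume$voxel_size,
            params = params, class = "pli_stack")
}

# closed-form detector intensity for a homogeneous column (used as the
# independent oracle in the tests and to document the forward model)
#' Closed-form signal of a homogeneous column
#'
#' `I(rho) = (I_T / 2) * (1 + sin(2 rho - 2 phi) * sin(delta_total))` where
#' `I_T` is the attenuated transmittance of the column.
#'
#' @param rho Polarizer angles, radians.
#' @param phi In-plane fiber direction, radians.
#' @param delta_total Accumulated retardance of the column, radians.
#' @param I_T Transmitted intensity (after absorption), counts.
#' @return Numeric vector of intensities.
#' @export
pli_signal <- function(rho, phi, delta_total, I_T) {
  I_T / 2 * (1 + sin(2 * rho - 2 * phi) * sin(delta_total))
}

#' Blur and downsample an image series to the camera pixel size
#'
#' Gaussian blur with `sigma = blur_factor * pixel_size` (circular
#' convolution computed in the Fourier domain, which preserves the image
#' mean exactly), followed by block-average downsampling by
#' `pixel_size / voxel_size` (must be an integer factor dividing the image
#' size).
#'
#' @param stack A `pli_stack` at voxel resolution.
#' @param params An `optics_params` list.
#' @return A `pli_stack` at camera resolution.
#' @export
downsample_blur <- function(stack, params = attr(stack, "params")) {
  stopifnot(inherits(stack, "pli_stack"))
  vs <- attr(stack, "pixel_size")
  f <- params$pixel_size / vs
  if (abs(f - round(f)) > 1e-9) {
    stop_validation("pixel_size must be an integer multiple of the voxel size")
  }
  f <- as.integer(round(f))
  nx <- dim(stack)[1]; ny <- dim(stack)[2]
  if (nx %% f != 0 || ny %% f != 0) {
    stop_validation("image dimensions must be divisible by the downsampling factor")
  }
  sigma <- params$blur_factor * params$pixel_size / vs  # in voxels
  gk <- function(n) {
    d <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
    k <- exp(-d^2 / (2 * sigma^2))
    k / sum(k)
  }
  Kx <- fft(gk(nx)); Ky <- fft(gk(ny))
  K2 <- outer(Kx, Ky)
  out <- array(NA_real_, c(nx / f, ny / f, dim(stack)[3]))
  for (k in seq_len(dim(stack)[3])) {
    img <- stack[, , k]
    if (sigma > 0) {
      img <- Re(fft(fft(img) * K2, inverse = TRUE)) / length(img)
    }
    # block average
    blk <- array(img, c(f, nx / f, f, ny / f))
    out[, , k] <- apply(blk, c(2, 4), mean)
  }
  structure(out, angles = attr(stack, "angles"),
            pixel_size = params$pixel_size, params = params,
            class = "pli_stack")
}

#' Add sensor noise to an image series
#'
#' Gaussian noise with variance `noise_gain * intensity` (a shot-noise-like
#' CCD model), independent per pixel and angle, mean-unbiased. Negative
#' intensities are clipped at zero with a warning. With `params$noise =
#' FALSE` the stack is returned unchanged.
#'
#' @param stack A `pli_stack`.
#' @param params An `optics_params` list.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return The noisy `pli_stack`.
#' @export
add_noise <- function(stack, params = attr(stack, "params"), seed) {
  stopifnot(inherits(stack, "pli_stack"))
  if (!isTRUE(params$noise)) return(stack)
  if (missing(seed) || is.null(seed)) {
    stop_validation("add_noise requires an explicit seed")
  }
  noisy <- withr::with_seed(as.integer(seed), {
    stack + rnorm(length(stack), sd = sqrt(params$noise_gain * pmax(stack, 0)))
  })
  if (any(noisy < 0)) {
    warn("negative intensities after noise clipped at 0")
    noisy[noisy < 0] <- 0
  }
  attributes(noisy) <- attributes(stack)
  noisy
}

#' Write an image series as multi-page TIFF (float32)
#'
#' @param stack A `pli_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "pli_stack"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_io("the 'tiff' package is required for TIFF export")
  }
  pages <- lapply(seq_len(dim(stack)[3]), function(k) {
    # tiff expects row-major images in [0, 1]; store raw counts as float
    t(stack[, , k])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write / read an image series as HDF5 with angle metadata
#'
#' @param stack A `pli_stack`.
#' @param path File path.
#' @return `path` invisibly; `read_stack_h5()` returns a `pli_stack`.
#' @export
write_stack_h5 <- function(stack, path) {
  stopifnot(inherits(stack, "pli_stack"))
  if (file.exists(path)) unlink(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stop_io(paste0("cannot create HDF5 file: ", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createDataset(path, "images", dims = dim(stack),
                         H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(unclass(stack), path, "images")
  rhdf5::h5write(attr(stack, "angles"), path, "angles")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(attr(stack, "pixel_size"), fid, "pixel_size")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_stack_h5
#' @export
read_stack_h5 <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  img <- rhdf5::h5read(path, "images")
  ang <- as.numeric(rhdf5::h5read(path, "angles"))
  attrs <- rhdf5::h5readAttributes(path, "/")
  structure(img, angles = ang,
            pixel_size = as.numeric(attrs$pixel_size),
            params = NULL, class = "pli_stack")
}

#' @export
print.pli_stack <- function(x, ...) {
  cat(sprintf(
    "# polarimetric image series: %d x %d pixels (%g um), %d angles\n",
    dim(x)[1], dim(x)[2], attr(x, "pixel_size"), dim(x)[3]
  ))
  invisible(x)
}
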