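# Orientation recovery from the measured sinusoidal signals. A discrete
# harmonic (Fourier) estimator: the signal of every pixel is projected onto
# the frequency-2 harmonics of the polarizer angle, giving the in-plane
# direction phi from the phase, |sin(delta_total)| from the relative
# modulation, and the inclination alpha from inverting the retardance
# formula delta = 2 pi t dn cos^2(alpha) / lambda. This is a single-view
# simplification of full tilting-stage orientation fitting ("rofl-lite").

#' Recover a fiber orientation map from an image series
#'
#' Per pixel, with `I(rho) = a (1 + sin(delta) sin(2 rho - 2 phi))`:
#' the discrete Fourier coefficients of `I` at frequency 2 give
#' `phi = atan2(-b_cos, b_sin) / 2` (mapped to `[0, pi)`) and
#' `|sin delta| = sqrt(b_cos^2 + b_sin^2) / a`. The inclination follows from
#' `cos^2(alpha) = delta * lambda / (2 pi * thickness * dn)`, clipped to
#' `[0, 1]`. Pixels without modulation (vertical fibers or background) and
#' pixels with unphysical modulation exceeding the mean are masked.
#'
#' @param stack A `pli_stack` (any resolution).
#' @param params An `optics_params`; `angles` must match the stack and be at
#'   least 3 equally spaced angles covering `[0, pi)`.
#' @param min_modulation Relative modulation below which the direction is
#'   considered undefined and masked.
#' @return A `pli_orientation_map`: tibble with one row per pixel, columns
#'   `i`, `j` (pixel indices), `x`, `y` (pixel centers, um), `mean`
#'   (transmitted mean intensity), `sin_delta`, `phi` (in `[0, pi)`),
#'   `alpha` (in `[0, pi/2]`), `valid`.
#' @export
recover_orientation <- function(stack, params = attr(stack, "params"),
                                min_modulation = 1e-4) {
  stopifnot(inherits(stack, "pli_stack"))
  rho <- attr(stack, "angles")
  if (length(rho) < 3) {
    stop_validation("at least 3 polarizer angles are required")
  }
  n <- length(rho)
  nx <- dim(stack)[1]; ny <- dim(stack)[2]
  flat <- matrix(stack, nx * ny, n)
  a <- rowMeans(flat)
  b_s <- 2 / n * as.numeric(flat %*% sin(2 * rho))
  b_c <- 2 / n * as.numeric(flat %*% cos(2 * rho))
  mod <- sqrt(b_s^2 + b_c^2)
  msin <- ifelse(a > 0, mod / a, 0)
  unphysical <- msin > 1 + 1e-6
  if (any(unphysical)) {
    warn(sprintf(
      "%d pixel(s) with modulation exceeding the mean intensity were masked",
      sum(unphysical)
    ))
  }
  phi <- (atan2(-b_c, b_s) / 2) %% pi
  delta <- asin(pmin(msin, 1))
  lam_um <- params$wavelength / 1000
  cos2a <- pmin(1, pmax(0, delta * lam_um /
                          (2 * pi * params$thickness * params$birefringence)))
  alpha <- acos(sqrt(cos2a))
  valid <- msin >= min_modulation & !unphysical & a > 0
  phi[!valid] <- NA_real_
  alpha[!valid] <- NA_real_
  ij <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  px <- attr(stack, "pixel_size")
  out <- tibble(
    i = ij$i, j = ij$j,
    x = (ij$i - 0.5) * px, y = (ij$j - 0.5) * px,
    mean = a, sin_delta = msin, phi = phi, alpha = alpha, valid = valid
  )
  structure(out, pixel_size = px, map_dim = c(nx, ny), params = params,
            class = c("pli_orientation_map", class(tibble())))
}

#' Color-code fiber orientations
#'
#' Antipodally symmetric color maps for unit direction vectors: `rgb` maps
#' a direction to `(|dx|, |dy|, |dz|)`; `hsv` maps the in-plane angle to the
#' hue (`hue = phi / pi`), the inclination to the saturation
#' (`cos(alpha)`), with full value.
#'
#' @param direction A unit 3-vector or an n x 3 matrix of unit row vectors.
#' @param mode `"rgb"` or `"hsv"`.
#' @return An n x 3 matrix of RGB values in `[0, 1]`.
#' @examples
#' orientation_to_color(c(0, 0, 1), "rgb")  # pure blue
#' @export
orientation_to_color <- function(direction, mode = c("rgb", "hsv")) {
  mode <- match.arg(mode)
  if (!is.matrix(direction)) direction <- matrix(direction, nrow = 1)
  if (ncol(direction) != 3) {
    stop_validation("direction must be a 3-vector or an n x 3 matrix")
  }
  nrm <- sqrt(rowSums(direction^2))
  if (any(!is.finite(nrm)) || any(nrm < 1e-12)) {
    stop_validation("directions must be nonzero vectors")
  }
  direction <- direction / nrm
  if (mode == "rgb") {
    out <- abs(direction)
  } else {
    phi <- atan2(direction[, 2], direction[, 1]) %% pi
    sat <- pmin(1, sqrt(direction[, 1]^2 + direction[, 2]^2))
    hex <- grDevices::hsv(h = phi / pi, s = sat, v = 1)
    out <- t(grDevices::col2rgb(hex)) / 255
  }
  colnames(out) <- c("r", "g", "b")
  unname(out)
}

#' Write an orientation map as HDF5 and as a flat-text vector field
#'
#' The HDF5 file stores `phi`, `alpha` and the validity mask as 2D
#' datasets; the text export is a table `x y phi alpha` (valid pixels only)
#' suitable for vector-field overlays.
#'
#' @param map A `pli_orientation_map`.
#' @param path Output path (`.h5` or text).
#' @param format `"h5"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_orientation_map <- function(map, path, format = c("h5", "text")) {
  stopifnot(inherits(map, "pli_orientation_map"))
  format <- match.arg(format)
  dims <- attr(map, "map_dim")
  if (format == "h5") {
    if (file.exists(path)) unlink(path)
    ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
    if (!isTRUE(ok)) stop_io(paste0("cannot create HDF5 file: ", path))
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    rhdf5::h5write(matrix(map$phi, dims[1], dims[2]), path, "phi")
    rhdf5::h5write(matrix(map$alpha, dims[1], dims[2]), path, "alpha")
    rhdf5::h5write(matrix(as.integer(map$valid), dims[1], dims[2]), path, "mask")
  } else {
    ok <- map[map$valid, ]
    writeLines(
      c("# x y phi alpha",
        sprintf("%.9g %.9g %.9g %.9g", ok$x, ok$y, ok$phi, ok$alpha)),
      path
    )
  }
  invisible(path)
}

#' Render an orientation map to an RGB raster (and optionally a PNG)
#'
#' @param map A `pli_orientation_map`.
#' @param mode Color mode, see [orientation_to_color()].
#' @param path Optional PNG output path.
#' @return An `nx x ny x 3` RGB array in `[0, 1]`, invisibly when `path`
#'   is given.
#' @export
orientation_map_rgb <- function(map, mode = c("hsv", "rgb"), path = NULL) {
  stopifnot(inherits(map, "pli_orientation_map"))
  mode <- match.arg(mode)
  dims <- attr(map, "map_dim")
  col <- matrix(0, nrow(map), 3)
  ok <- map$valid
  if (any(ok)) {
    dirs <- cbind(
      cos(map$phi[ok]) * cos(map$alpha[ok]),
      sin(map$phi[ok]) * cos(map$alpha[ok]),
      sin(map$alpha[ok])
    )
    col[ok, ] <- orientation_to_color(dirs, mode)
  }
  arr <- array(0, c(dims[1], dims[2], 3))
  for (k in 1:3) arr[, , k] <- matrix(col[, k], dims[1], dims[2])
  if (!is.null(path)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop_io("the 'png' package is required for PNG export")
    }
    # png files store rows top-down; transpose to image convention
    img <- aperm(arr, c(2, 1, 3))[dims[2]:1, , , drop = FALSE]
    png::writePNG(img, path)
    return(invisible(arr))
  }
  arr
}
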