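#' Interpolate a fiber through control points with a cubic spline
#'
#' Coordinates and radii are interpolated with the same scheme: a cubic
#' spline in a common curve parameter. By default the parameter is the
#' control-point index (uniform parameterization); chord-length
#' parameterization is available via `parameterization = "chord"`. The sampled
#' curve passes exactly through every control point and has
#' `(n_controls - 1) * samples_per_segment + 1` points.
#'
#' Boundary conditions: `"cubic"` (default) fits an exact cubic through the
#' four points at each end, so control points sampled from a single cubic
#' polynomial reproduce that polynomial exactly; `"natural"` uses zero end
#' curvature instead.
#'
#' @param controls A data frame with columns `x`, `y`, `z`, `r` giving the
#'   control points (micrometres), in order along the fiber.
#' @param samples_per_segment Positive integer: output samples per control
#'   segment.
#' @param parameterization `"index"` (default) or `"chord"`.
#' @param boundary End condition: `"cubic"` (default) or `"natural"`.
#' @param fiber,group Identifier and group path for the generated fiber.
#' @return A `fiber_phantom` with one fiber.
#' @examples
#' ctrl <- data.frame(x = c(0, 10, 20), y = c(0, 5, 0), z = 0, r = 2)
#' spline_fiber(ctrl, 10)
#' @export
spline_fiber <- function(controls, samples_per_segment = 10,
                         parameterization = c("index", "chord"),
                         boundary = c("cubic", "natural"),
                         fiber = "fiber_1", group = "") {
  parameterization <- match.arg(parameterization)
  boundary <- match.arg(boundary)
  method <- if (boundary == "cubic") "fmm" else "natural"
  controls <- as.data.frame(controls)
  needed <- c("x", "y", "z", "r")
  if (!all(needed %in% names(controls))) {
    stop_validation("controls must have columns x, y, z, r")
  }
  n <- nrow(controls)
  if (n < 2) stop_validation("at least 2 control points are required")
  dup <- with(controls, which(
    diff(x) == 0 & diff(y) == 0 & diff(z) == 0
  ))
  if (length(dup)) {
    stop_validation(paste0(
      "duplicated consecutive control points at position ", dup[1] + 1
    ))
  }
  spp <- as.integer(samples_per_segment)
  if (is.na(spp) || spp < 1) {
    stop_validation("samples_per_segment must be a positive integer")
  }
  u <- if (parameterization == "index") {
    seq_len(n) - 1
  } else {
    c(0, cumsum(sqrt(diff(controls$x)^2 + diff(controls$y)^2 +
                       diff(controls$z)^2)))
  }
  # per-segment uniform subdivision of the parameter, node values kept exact
  uout <- unlist(lapply(seq_len(n - 1), function(k) {
    seq(u[k], u[k + 1], length.out = spp + 1)[-(spp + 1)]
  }))
  uout <- c(uout, u[n])
  interp <- function(v) {
    if (n == 2) {
      # any cubic interpolant through two points degenerates to the chord
      v[1] + (uout - u[1]) / (u[2] - u[1]) * (v[2] - v[1])
    } else {
      spline(u, v, xout = uout, method = method)$y
    }
  }
  out <- lapply(controls[needed], interp)
  # interpolation can undershoot slightly; radii stay physical
  out$r <- pmax(out$r, 0)
  # control nodes are reproduced exactly
  node_idx <- seq(1, length(uout), by = spp)
  for (nm in needed) out[[nm]][node_idx] <- controls[[nm]]
  fiber_points(out$x, out$y, out$z, out$r, fiber = fiber, group = group)
}
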