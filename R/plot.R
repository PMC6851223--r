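# Plotting and broom-style summaries.

#' @importFrom ggplot2 autoplot ggplot aes geom_path geom_raster coord_equal
#'   scale_fill_identity labs theme_minimal
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Plot a fiber phantom (xy projection)
#'
#' Draws each fiber center line, colored by its local in-plane orientation
#' (antipodally symmetric HSV hue), over the xy plane.
#'
#' @param object A `fiber_phantom`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fiber_phantom <- function(object, ...) {
  seg <- object %>%
    group_by(.data$fiber) %>%
    mutate(dx = lead(.data$x) - .data$x, dy = lead(.data$y) - .data$y) %>%
    ungroup() %>%
    mutate(
      hue = (atan2(.data$dy, .data$dx) %% pi) / pi,
      col = grDevices::hsv(ifelse(is.na(.data$hue), 0, .data$hue), 1, 1)
    )
  ggplot(seg, aes(x = .data$x, y = .data$y, group = .data$fiber)) +
    geom_path(aes(colour = .data$col), linewidth = 0.3) +
    ggplot2::scale_colour_identity() +
    coord_equal() +
    labs(x = "x [µm]", y = "y [µm]") +
    theme_minimal()
}

#' Plot a recovered fiber orientation map
#'
#' @param object A `pli_orientation_map`.
#' @param mode Color mode, see [orientation_to_color()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pli_orientation_map <- function(object, mode = c("hsv", "rgb"), ...) {
  mode <- match.arg(mode)
  df <- as_tibble(object)
  df$col <- "#000000"
  ok <- df$valid
  if (any(ok)) {
    dirs <- cbind(
      cos(df$phi[ok]) * cos(df$alpha[ok]),
      sin(df$phi[ok]) * cos(df$alpha[ok]),
      sin(df$alpha[ok])
    )
    rgbm <- orientation_to_color(dirs, mode)
    df$col[ok] <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3])
  }
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$col)) +
    geom_raster() +
    scale_fill_identity() +
    coord_equal() +
    labs(x = "x [µm]", y = "y [µm]") +
    theme_minimal()
}

#' Tidy a recovered orientation map
#'
#' @param x A `pli_orientation_map`.
#' @param ... Unused.
#' @return A plain tibble of per-pixel records.
#' @export
tidy.pli_orientation_map <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  attr(out, "pixel_size") <- NULL
  attr(out, "params") <- NULL
  out
}

#' One-row summary of a recovered orientation map
#'
#' @inheritParams tidy.pli_orientation_map
#' @return A one-row tibble: pixel counts, valid fraction, median direction
#'   and inclination over valid pixels.
#' @export
glance.pli_orientation_map <- function(x, ...) {
  ok <- x$valid
  tibble(
    n_pixels = nrow(x),
    n_valid = sum(ok),
    valid_fraction = mean(ok),
    median_phi = stats::median(x$phi[ok]),
    median_alpha = stats::median(x$alpha[ok]),
    mean_intensity = mean(x$mean)
  )
}

#' One-row summary of a fiber phantom
#'
#' @param x A `fiber_phantom`.
#' @param ... Unused.
#' @return A one-row tibble: fiber/point/group counts, bounding box, radii.
#' @export
glance.fiber_phantom <- function(x, ...) {
  tibble(
    n_fibers = n_fibers(x),
    n_points = nrow(x),
    n_groups = length(setdiff(unique(x$group), "")),
    xmin = min(x$x), xmax = max(x$x),
    ymin = min(x$y), ymax = max(x$y),
    zmin = min(x$z), zmax = max(x$z),
    r_min = min(x$r), r_max = max(x$r)
  )
}
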