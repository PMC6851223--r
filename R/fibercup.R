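# Programmatic construction of a Fiber Cup style crossing phantom: seven
# fiber bundles on a circular plate with a straight transverse bundle, a
# three-bundle merge crossing it, a bending bundle, a symmetric equal-density
# crossing, and a curved (fanning) bundle. The center-line control points are
# this package's versioned layout: they reproduce the topology of the
# classic phantom (crossings, merge, bending) without claiming the original
# hardware geometry.

default_fibercup_bundles <- function() {
  ctrl <- function(x, y) data.frame(x = x, y = y, z = 0)
  list(
    # bending (C-shaped) bundle along the left/lower-left edge
    bundle_1 = ctrl(380 * cos(seq(120, 240, by = 30) * pi / 180),
                    380 * sin(seq(120, 240, by = 30) * pi / 180)),
    # straight diagonal bundle: symmetric equal-density crossing with bundle 3
    bundle_2 = ctrl(c(180, 280, 380), c(-430, -15, 400)),
    # straight transverse bundle through the plate center
    bundle_3 = ctrl(c(-480, 0, 480), c(0, 0, 0)),
    # bundles 4-6 merge into one vertical path at x = -260 and cross bundle 3
    bundle_4 = ctrl(c(-440, -360, -290, -262, -260, -260, -260),
                    c(-350, -280, -190, -110, 0, 200, 380)),
    bundle_5 = ctrl(c(-80, -160, -230, -258, -260, -260, -260),
                    c(-440, -350, -220, -110, 0, 200, 380)),
    bundle_6 = ctrl(c(-260, -260, -260, -260, -260, -260),
                    c(-470, -300, -150, 0, 200, 380)),
    # curved bundle fanning across the top-right quadrant
    bundle_7 = ctrl(c(60, 120, 210, 330, 430),
                    c(430, 330, 260, 230, 150))
  )
}

#' Configuration for the Fiber Cup phantom
#'
#' Defaults: bundle diameter 120, fiber diameter 1.5, surface gap between
#' fibers 1.5 (center spacing 3.0), plate diameter 1000, 42 sample points
#' per fiber (all micrometres). `bundles` must name exactly 7 center-line
#' control tables (columns `x`, `y`, `z`; constant bundle radius is applied).
#'
#' @param bundle_diameter,fiber_diameter,fiber_gap,plate_diameter Geometry
#'   parameters in micrometres.
#' @param samples_per_fiber Data points per fiber after filling.
#' @param bundles Named list of 7 control-point data frames.
#' @return A `fibercup_config` list.
#' @export
fibercup_config <- function(bundle_diameter = 120, fiber_diameter = 1.5,
                            fiber_gap = 1.5, plate_diameter = 1000,
                            samples_per_fiber = 42,
                            bundles = default_fibercup_bundles()) {
  lens <- c(bundle_diameter, fiber_diameter, fiber_gap, plate_diameter)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop_validation("all Fiber Cup lengths must be positive")
  }
  if (!is.list(bundles) || length(bundles) != 7) {
    stop_validation("a Fiber Cup configuration needs exactly 7 bundle definitions")
  }
  if (is.null(names(bundles)) || any(names(bundles) == "")) {
    names(bundles) <- sprintf("bundle_%d", seq_along(bundles))
  }
  structure(
    list(
      bundle_diameter = bundle_diameter,
      fiber_diameter = fiber_diameter,
      fiber_gap = fiber_gap,
      plate_diameter = plate_diameter,
      samples_per_fiber = as.integer(samples_per_fiber),
      bundles = bundles
    ),
    class = "fibercup_config"
  )
}

#' Read / write a Fiber Cup configuration as structured text (YAML)
#'
#' @param path File path.
#' @return `read_fibercup_config()` returns a `fibercup_config`;
#'   `write_fibercup_config()` returns `path` invisibly.
#' @export
read_fibercup_config <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  y <- yaml::read_yaml(path)
  bundles <- lapply(y$bundles, function(b) as.data.frame(b))
  fibercup_config(
    bundle_diameter = y$bundle_diameter %||% 120,
    fiber_diameter = y$fiber_diameter %||% 1.5,
    fiber_gap = y$fiber_gap %||% 1.5,
    plate_diameter = y$plate_diameter %||% 1000,
    samples_per_fiber = y$samples_per_fiber %||% 42,
    bundles = bundles
  )
}

#' @rdname read_fibercup_config
#' @param config A `fibercup_config`.
#' @export
write_fibercup_config <- function(config, path) {
  stopifnot(inherits(config, "fibercup_config"))
  y <- config
  class(y) <- NULL
  y$bundles <- lapply(y$bundles, function(b) as.list(as.data.frame(b)))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the Fiber Cup bundle envelopes
#'
#' Interpolates each configured center line with a natural cubic spline
#' ([spline_fiber()], chord-length parameterization) at constant radius
#' `bundle_diameter / 2`, giving 7 envelope fibers. Envelopes are allowed to
#' overlap (bundles 4-6 merge into one path).
#'
#' @param config A `fibercup_config`.
#' @return A `fiber_phantom` with the 7 envelopes (groups `bundle_1` ...).
#' @examples
#' cup <- build_fibercup(fibercup_config())
#' n_fibers(cup)
#' @export
build_fibercup <- function(config = fibercup_config()) {
  stopifnot(inherits(config, "fibercup_config"))
  R <- config$bundle_diameter / 2
  n_out <- config$samples_per_fiber
  envs <- purrr::imap(config$bundles, function(b, nm) {
    b <- as.data.frame(b)
    if (!all(c("x", "y") %in% names(b))) {
      stop_validation(paste0("bundle '", nm, "' needs columns x, y (and optionally z)"))
    }
    if (is.null(b$z)) b$z <- 0
    b$r <- R
    nseg <- nrow(b) - 1
    spp <- max(1L, ceiling((n_out - 1) / nseg))
    fb <- spline_fiber(b, samples_per_segment = spp,
                       parameterization = "chord", fiber = nm, group = nm)
    # resample to exactly n_out points along the spline's own samples
    idx <- unique(round(seq(1, nrow(fb), length.out = n_out)))
    fb <- fb[idx, ]
    fb$point <- seq_len(nrow(fb))
    fb
  })
  as_fiber_phantom(bind_rows(envs))
}

#' Fill the Fiber Cup envelopes with fibers
#'
#' Each envelope is filled with [fill_bundle()] using
#' `r_fiber = fiber_diameter / 2` and center spacing
#' `fiber_diameter + fiber_gap`. Overlapping envelopes multiply the local
#' fiber density (the merged bundles 4-6 are three times denser than the
#' transverse bundle where they cross it).
#'
#' @param phantom Envelope phantom from [build_fibercup()].
#' @param config The matching `fibercup_config`.
#' @return A `fiber_phantom` of all child fibers, grouped per bundle.
#' @export
fill_fibercup <- function(phantom = build_fibercup(config),
                          config = fibercup_config()) {
  stopifnot(inherits(config, "fibercup_config"))
  phantom <- as_fiber_phantom(phantom)
  r_fiber <- config$fiber_diameter / 2
  spacing <- config$fiber_diameter + config$fiber_gap
  filled <- lapply(unique(phantom$fiber), function(fid) {
    fill_bundle(phantom[phantom$fiber == fid, ], r_fiber = r_fiber,
                spacing = spacing, group = phantom$group[phantom$fiber == fid][1])
  })
  as_fiber_phantom(bind_rows(filled))
}
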