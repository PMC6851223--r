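# Bundle filling: seed a triangular (hexagonal) grid in the minimum-radius
# cross-section of a parent envelope, transport it along the trajectory with
# Rodrigues-rotated frames, and scale the in-plane offsets with the local
# envelope radius.

#' Triangular seed grid for bundle filling
#'
#' Seeds lie on a hexagonal lattice with nearest-neighbor center distance
#' `spacing`. The bundle axis sits at the centroid of a lattice triangle (no
#' seed on the axis itself); a seed is kept when its center lies within
#' `R_ref` of the axis. This grid convention is the one calibrated against
#' the fiber counts the filling procedure is expected to reproduce (see the
#' methods vignette): a user-specified minimum surface-to-surface distance
#' `d` between fibers of radius `r` corresponds to
#' `spacing = d + 2 r`.
#'
#' @param R_ref Reference (minimum) envelope radius, micrometres.
#' @param r_fiber Child fiber radius, micrometres.
#' @param spacing Center-to-center seed distance, micrometres.
#' @return A tibble with columns `u`, `v`: in-plane offsets from the axis.
#' @examples
#' triangular_seed_grid(R_ref = 1, r_fiber = 0.1, spacing = 0.4)
#' @export
triangular_seed_grid <- function(R_ref, r_fiber, spacing) {
  if (!is.numeric(R_ref) || R_ref <= 0) stop_validation("R_ref must be > 0")
  if (!is.numeric(r_fiber) || r_fiber <= 0) {
    stop_validation("r_fiber must be > 0")
  }
  if (!is.numeric(spacing) || spacing <= 0) {
    stop_validation("spacing must be > 0")
  }
  if (r_fiber > R_ref) {
    stop_validation("r_fiber exceeds R_ref: the envelope has no interior to fill")
  }
  s <- spacing
  # rows are s*sqrt(3)/2 apart and axial u-coordinates shear with j,
  # so the index range must cover twice the disc radius
  nmax <- ceiling(2 * R_ref / s) + 2
  ij <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  # lattice point (i, j) minus the triangle centroid (s/2, s*sqrt(3)/6)
  u <- (ij$i + ij$j / 2) * s - s / 2
  v <- ij$j * s * sqrt(3) / 2 - s * sqrt(3) / 6
  keep <- sqrt(u^2 + v^2) <= R_ref * (1 + 1e-9) + 1e-12
  seeds <- tibble(u = u[keep], v = v[keep])
  seeds[order(seeds$u^2 + seeds$v^2, atan2(seeds$v, seeds$u)), ]
}

#' Orthonormal moving frames along a fiber
#'
#' One frame per data point: the tangent is the normalized central difference
#' (one-sided at the ends); the two in-plane normals are transported from
#' point to point by rotating with [rodrigues_rotate()] about the axis
#' `t_i x t_{i+1}` through the angle between consecutive tangents, which
#' keeps torsion-free alignment of the seed grid along the trajectory.
#'
#' The initial `normal_u` is the global coordinate axis least aligned with
#' the first tangent, orthogonalized against it (deterministic). When
#' consecutive tangents are antiparallel the rotation axis is undefined; an
#' arbitrary perpendicular axis is used and a warning is emitted.
#'
#' @param parent A `fiber_phantom` containing exactly one fiber.
#' @return A tibble with one row per data point: `point`, origin (`ox,oy,oz`),
#'   tangent (`tx,ty,tz`), and normals (`ux,uy,uz`, `vx,vy,vz`).
#' @export
transport_frames <- function(parent) {
  parent <- as_fiber_phantom(parent)
  if (n_fibers(parent) != 1) {
    stop_validation("transport_frames expects a single-fiber phantom")
  }
  p <- cbind(parent$x, parent$y, parent$z)
  n <- nrow(p)
  # central-difference tangents, one-sided at the ends
  tang <- rbind(
    p[2, ] - p[1, ],
    if (n > 2) p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE],
    p[n, ] - p[n - 1, ]
  )
  tang <- tang / sqrt(rowSums(tang^2))
  # deterministic initial normal. Derived from the trajectory itself (first
  # tangent turn), which makes the fill equivariant under rigid transforms;
  # perfectly straight fibers have no intrinsic transverse direction, so
  # they fall back to the global axis least aligned with the tangent.
  t0 <- tang[1, ]
  u <- NULL
  for (i in seq_len(n - 1)) {
    turn <- tang[i + 1, ] - tang[i, ]
    perp <- turn - sum(turn * t0) * t0
    if (sqrt(sum(perp^2)) > 1e-9) {
      u <- perp / sqrt(sum(perp^2))
      break
    }
  }
  if (is.null(u)) {
    eidx <- which.min(abs(t0))
    e <- c(0, 0, 0); e[eidx] <- 1
    u <- e - sum(e * t0) * t0
    u <- u / sqrt(sum(u^2))
  }
  v <- c(
    t0[2] * u[3] - t0[3] * u[2],
    t0[3] * u[1] - t0[1] * u[3],
    t0[1] * u[2] - t0[2] * u[1]
  )
  U <- matrix(NA_real_, n, 3); V <- matrix(NA_real_, n, 3)
  U[1, ] <- u; V[1, ] <- v
  for (i in seq_len(n - 1)) {
    a <- tang[i, ]; b <- tang[i + 1, ]
    ax <- c(
      a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1]
    )
    sina <- sqrt(sum(ax^2))
    cosa <- sum(a * b)
    if (sina < 1e-12) {
      if (cosa < 0) {
        warn("antiparallel consecutive tangents: rotation axis is undefined, using an arbitrary perpendicular axis")
        ax <- U[i, ]   # any vector perpendicular to the tangent
        ang <- pi
      } else {
        U[i + 1, ] <- U[i, ]; V[i + 1, ] <- V[i, ]
        next
      }
    } else {
      ax <- ax / sina
      ang <- atan2(sina, cosa)
    }
    U[i + 1, ] <- rodrigues_rotate(U[i, ], ax, ang)
    V[i + 1, ] <- rodrigues_rotate(V[i, ], ax, ang)
  }
  tibble(
    point = parent$point,
    ox = p[, 1], oy = p[, 2], oz = p[, 3],
    tx = tang[, 1], ty = tang[, 2], tz = tang[, 3],
    ux = U[, 1], uy = U[, 2], uz = U[, 3],
    vx = V[, 1], vy = V[, 2], vz = V[, 3]
  )
}

# internal: reference radius = minimum positive radius along the parent
# (zero radii, e.g. at tapered endpoints, are excluded so the fill does not
# degenerate to the axis)
reference_radius <- function(parent) {
  pos <- parent$r[parent$r > 0]
  if (!length(pos)) {
    stop_validation("parent fiber has no positive radius to fill")
  }
  min(pos)
}

#' Fill a bundle envelope with child fibers
#'
#' Child fibers are seeded with [triangular_seed_grid()] in the cross-section
#' with the minimum (positive) radius and transported along the parent with
#' [transport_frames()]. At parent point `j` with radius `R_j`, the in-plane
#' offsets scale by `R_j / R_ref`, so the inter-fiber distance grows with the
#' envelope radius. All children have the constant radius `r_fiber` and are
#' returned as one group named after the parent fiber.
#'
#' If no grid seed fits inside the reference cross-section, a single child
#' running along the parent axis is returned.
#'
#' @param parent A single-fiber `fiber_phantom` (the envelope).
#' @param r_fiber Child fiber radius, micrometres.
#' @param spacing Center-to-center distance between neighboring children at
#'   the reference cross-section, micrometres. A minimum surface gap `d`
#'   corresponds to `spacing = d + 2 * r_fiber`. A warning is emitted when
#'   `spacing < 2 * r_fiber` since non-intersection is then no longer
#'   guaranteed.
#' @param group Group path for the children; default the parent fiber id.
#' @return A `fiber_phantom` with the child fibers.
#' @examples
#' env <- parametric_fiber("t", "0", "0", "1", 0, 100, 20)
#' fill_bundle(env, r_fiber = 0.1, spacing = 0.4)
#' @export
fill_bundle <- function(parent, r_fiber, spacing, group = NULL) {
  parent <- as_fiber_phantom(parent)
  if (n_fibers(parent) != 1) {
    stop_validation("fill_bundle expects a single-fiber phantom as parent")
  }
  if (!is.numeric(r_fiber) || r_fiber <= 0) {
    stop_validation("r_fiber must be > 0")
  }
  if (!is.numeric(spacing) || spacing <= 0) {
    stop_validation("spacing must be > 0")
  }
  if (spacing < 2 * r_fiber) {
    warn("spacing is below the fiber diameter: child fibers may intersect")
  }
  R_ref <- reference_radius(parent)
  seeds <- triangular_seed_grid(R_ref, r_fiber, spacing)
  if (nrow(seeds) == 0) seeds <- tibble(u = 0, v = 0)
  if (is.null(group)) group <- parent$fiber[1]
  fr <- transport_frames(parent)
  scale <- parent$r / R_ref
  n_pts <- nrow(fr)
  n_child <- nrow(seeds)
  # child k at point j: origin_j + (R_j/R_ref) * (u_k * U_j + v_k * V_j)
  su <- rep(seeds$u, each = n_pts)
  sv <- rep(seeds$v, each = n_pts)
  sc <- rep(scale, times = n_child)
  out <- tibble(
    group = group,
    fiber = rep(sprintf("%s_f%04d", parent$fiber[1], seq_len(n_child)),
                each = n_pts),
    point = rep(fr$point, times = n_child),
    x = rep(fr$ox, n_child) + sc * (su * rep(fr$ux, n_child) + sv * rep(fr$vx, n_child)),
    y = rep(fr$oy, n_child) + sc * (su * rep(fr$uy, n_child) + sv * rep(fr$vy, n_child)),
    z = rep(fr$oz, n_child) + sc * (su * rep(fr$uz, n_child) + sv * rep(fr$vz, n_child)),
    r = r_fiber
  )
  as_fiber_phantom(out)
}
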