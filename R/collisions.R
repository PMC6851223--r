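# Fiber-fiber collision detection. Fibers are capsule chains: a collision is
# a pair of segments from different fibers whose axis distance falls below
# the sum of the local radii (minus a tolerance). A uniform-grid broad phase
# prunes segment pairs; the narrow phase is the closed-form clamped
# segment-segment minimum distance, fully vectorized.

# internal: segment table of a phantom
phantom_segments <- function(phantom) {
  phantom %>%
    group_by(.data$fiber) %>%
    mutate(
      bx = lead(.data$x), by = lead(.data$y), bz = lead(.data$z),
      rb = lead(.data$r)
    ) %>%
    filter(!is.na(.data$bx)) %>%
    ungroup() %>%
    transmute(
      fiber = .data$fiber, seg = .data$point,
      ax = .data$x, ay = .data$y, az = .data$z, ra = .data$r,
      bx = .data$bx, by = .data$by, bz = .data$bz, rb = .data$rb
    )
}

# internal: minimum distance between segment pairs (Lumelsky clamping),
# vectorized over rows of two aligned segment tables. Returns the distance,
# the two closest-approach parameters, and the midpoint of closest approach.
segment_pair_distance <- function(s1, s2) {
  d1x <- s1$bx - s1$ax; d1y <- s1$by - s1$ay; d1z <- s1$bz - s1$az
  d2x <- s2$bx - s2$ax; d2y <- s2$by - s2$ay; d2z <- s2$bz - s2$az
  wx <- s1$ax - s2$ax; wy <- s1$ay - s2$ay; wz <- s1$az - s2$az
  A <- d1x^2 + d1y^2 + d1z^2
  B <- d1x * d2x + d1y * d2y + d1z * d2z
  C <- d2x^2 + d2y^2 + d2z^2
  D <- d1x * wx + d1y * wy + d1z * wz
  E <- d2x * wx + d2y * wy + d2z * wz
  den <- A * C - B^2
  s <- ifelse(den > 1e-12 * A * C, (B * E - C * D) / den, 0)
  s <- pmin(1, pmax(0, s))
  t <- ifelse(C > 0, (B * s + E) / C, 0)
  t <- pmin(1, pmax(0, t))
  s <- ifelse(A > 0, (B * t - D) / A, 0)
  s <- pmin(1, pmax(0, s))
  px <- s1$ax + s * d1x; py <- s1$ay + s * d1y; pz <- s1$az + s * d1z
  qx <- s2$ax + t * d2x; qy <- s2$ay + t * d2y; qz <- s2$az + t * d2z
  list(
    dist = sqrt((px - qx)^2 + (py - qy)^2 + (pz - qz)^2),
    s = s, t = t,
    x = (px + qx) / 2, y = (py + qy) / 2, z = (pz + qz) / 2
  )
}

#' Detect colliding fiber pairs
#'
#' Reports every unordered pair of distinct fibers whose minimum
#' segment-to-segment axis distance is smaller than the sum of the local
#' radii minus `tolerance`. Radii are interpolated linearly along segments at
#' the closest-approach parameters. Results are ordered lexicographically by
#' fiber ids; the reported location is the midpoint of the closest approach.
#'
#' @param phantom A `fiber_phantom`.
#' @param tolerance Non-negative overlap tolerance, micrometres: shallower
#'   interpenetrations than this are ignored.
#' @return A tibble with columns `fiber_a`, `fiber_b`, `distance`,
#'   `clearance` (distance minus radii sum; negative = overlap), and the
#'   closest-approach location `x`, `y`, `z`.
#' @examples
#' a <- fiber_points(c(-5, 5), c(0, 0), c(0, 0), c(1, 1), "a")
#' b <- fiber_points(c(0, 0), c(-5, 5), c(0.5, 0.5), c(1, 1), "b")
#' detect_collisions(bind_phantoms(a, b))
#' @export
detect_collisions <- function(phantom, tolerance = 0) {
  phantom <- as_fiber_phantom(phantom)
  if (!is.numeric(tolerance) || tolerance < 0) {
    stop_validation("tolerance must be >= 0")
  }
  seg <- phantom_segments(phantom)
  empty <- tibble(
    fiber_a = character(), fiber_b = character(),
    distance = numeric(), clearance = numeric(),
    x = numeric(), y = numeric(), z = numeric()
  )
  if (nrow(seg) < 2) return(empty)
  rmax <- max(seg$ra, seg$rb)
  # broad phase: bin segment AABBs (inflated by the largest radius) on a grid
  # whose cell size covers the largest AABB, so each box spans <= 2 cells/axis
  lo <- cbind(pmin(seg$ax, seg$bx), pmin(seg$ay, seg$by), pmin(seg$az, seg$bz)) - rmax
  hi <- cbind(pmax(seg$ax, seg$bx), pmax(seg$ay, seg$by), pmax(seg$az, seg$bz)) + rmax
  cell <- max(hi - lo, 1e-6)
  key_parts <- lapply(1:3, function(k) {
    list(lo = floor(lo[, k] / cell), hi = floor(hi[, k] / cell))
  })
  idx <- seq_len(nrow(seg))
  entries <- list()
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    cx <- if (dx == 0) key_parts[[1]]$lo else key_parts[[1]]$hi
    cy <- if (dy == 0) key_parts[[2]]$lo else key_parts[[2]]$hi
    cz <- if (dz == 0) key_parts[[3]]$lo else key_parts[[3]]$hi
    entries[[length(entries) + 1]] <-
      tibble(seg_id = idx, key = paste(cx, cy, cz))
  }
  entries <- distinct(bind_rows(entries))
  # candidate pairs: segments sharing a cell, different fibers
  pairs <- entries %>%
    dplyr::inner_join(entries, by = "key", relationship = "many-to-many") %>%
    filter(.data$seg_id.x < .data$seg_id.y) %>%
    distinct(.data$seg_id.x, .data$seg_id.y)
  if (nrow(pairs) == 0) return(empty)
  i <- pairs$seg_id.x; j <- pairs$seg_id.y
  diff_fiber <- seg$fiber[i] != seg$fiber[j]
  i <- i[diff_fiber]; j <- j[diff_fiber]
  if (!length(i)) return(empty)
  nd <- segment_pair_distance(seg[i, ], seg[j, ])
  r1 <- seg$ra[i] + nd$s * (seg$rb[i] - seg$ra[i])
  r2 <- seg$ra[j] + nd$t * (seg$rb[j] - seg$ra[j])
  clearance <- nd$dist - (r1 + r2)
  # relative epsilon so exact tangency is never misreported as overlap
  hit <- clearance < -(tolerance + 1e-9 * (r1 + r2))
  if (!any(hit)) return(empty)
  res <- tibble(
    fiber_a = pmin(seg$fiber[i], seg$fiber[j])[hit],
    fiber_b = pmax(seg$fiber[i], seg$fiber[j])[hit],
    distance = nd$dist[hit],
    clearance = clearance[hit],
    x = nd$x[hit], y = nd$y[hit], z = nd$z[hit]
  )
  # one row per fiber pair: the deepest contact
  res %>%
    arrange(.data$fiber_a, .data$fiber_b, .data$clearance) %>%
    group_by(.data$fiber_a, .data$fiber_b) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$fiber_a, .data$fiber_b)
}
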