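# Independent oracles used across the suite. These deliberately take
# different computational routes than the package internals.

# axis-angle rotation matrix, built explicitly (I cos + skew sin + outer):
# oracle for rodrigues_rotate
rotation_matrix_oracle <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) * cos(angle) + sin(angle) * K + (1 - cos(angle)) * outer(k, k)
}

# exact minimum distance between two 3D segments by enumerating the KKT
# cases of the convex quadratic on the unit box: interior stationary point,
# the four edges (1D clamped minimizations), and the four corners
segment_distance_oracle <- function(a1, b1, a2, b2) {
  d1 <- b1 - a1; d2 <- b2 - a2; w <- a1 - a2
  A <- sum(d1 * d1); B <- sum(d1 * d2); C <- sum(d2 * d2)
  D <- sum(d1 * w); E <- sum(d2 * w)
  f <- function(s, t) sqrt(sum((w + s * d1 - t * d2)^2))
  cand <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  clamp <- function(x) min(1, max(0, x))
  # edges: minimize over one parameter with the other fixed
  if (A > 0) {
    cand <- c(cand, list(c(clamp(-D / A), 0), c(clamp((B - D) / A), 1)))
  }
  if (C > 0) {
    cand <- c(cand, list(c(0, clamp(E / C)), c(1, clamp((B + E) / C))))
  }
  den <- A * C - B^2
  if (den > 1e-14 * max(A * C, 1)) {
    s0 <- (B * E - C * D) / den
    t0 <- (A * E - B * D) / den
    if (s0 >= 0 && s0 <= 1 && t0 >= 0 && t0 <= 1) {
      cand <- c(cand, list(c(s0, t0)))
    }
  }
  vals <- vapply(cand, function(st) f(st[1], st[2]), 0)
  best <- which.min(vals)
  list(dist = vals[best], s = cand[[best]][1], t = cand[[best]][2])
}

# brute-force collision detection over every segment pair of distinct
# fibers: oracle for detect_collisions
brute_force_collisions <- function(phantom, tolerance = 0) {
  sp <- split(phantom, phantom$fiber)
  ids <- names(sp)
  hits <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      fa <- sp[[i]]; fb <- sp[[j]]
      collided <- FALSE
      for (si in seq_len(nrow(fa) - 1)) {
        for (sj in seq_len(nrow(fb) - 1)) {
          a1 <- c(fa$x[si], fa$y[si], fa$z[si])
          b1 <- c(fa$x[si + 1], fa$y[si + 1], fa$z[si + 1])
          a2 <- c(fb$x[sj], fb$y[sj], fb$z[sj])
          b2 <- c(fb$x[sj + 1], fb$y[sj + 1], fb$z[sj + 1])
          o <- segment_distance_oracle(a1, b1, a2, b2)
          ra <- fa$r[si] + o$s * (fa$r[si + 1] - fa$r[si])
          rb <- fb$r[sj] + o$t * (fb$r[sj + 1] - fb$r[sj])
          # same tangency epsilon as the documented collision semantics
          if (o$dist < ra + rb - tolerance - 1e-9 * (ra + rb)) {
            collided <- TRUE
          }
        }
      }
      if (collided) {
        hits[[length(hits) + 1]] <-
          sort(c(ids[i], ids[j]))
      }
    }
  }
  if (!length(hits)) return(character(0))
  sort(vapply(hits, function(h) paste(h, collapse = "|"), ""))
}

# exhaustive lattice enumeration over the bounding box: oracle for
# triangular_seed_grid counts (same documented convention, independent loop)
lattice_count_oracle <- function(R_ref, spacing) {
  s <- spacing
  count <- 0
  j <- -ceiling(4 * R_ref / s)
  while (j <= ceiling(4 * R_ref / s)) {
    v <- j * s * sqrt(3) / 2 - s * sqrt(3) / 6
    i <- -ceiling(4 * R_ref / s)
    while (i <= ceiling(4 * R_ref / s)) {
      u <- (i + j / 2) * s - s / 2
      if (u * u + v * v <= (R_ref * (1 + 1e-9))^2) count <- count + 1
      i <- i + 1
    }
    j <- j + 1
  }
  count
}

# textbook natural cubic spline via the tridiagonal second-derivative
# system: oracle for spline_fiber(boundary = "natural")
natural_spline_oracle <- function(u, y, uout) {
  n <- length(u)
  h <- diff(u)
  rhs <- 6 * diff(diff(y) / h)
  A <- matrix(0, n - 2, n - 2)
  for (k in seq_len(n - 2)) {
    A[k, k] <- 2 * (h[k] + h[k + 1])
    if (k > 1) A[k, k - 1] <- h[k]
    if (k < n - 2) A[k, k + 1] <- h[k + 1]
  }
  m <- c(0, solve(A, rhs), 0)  # second derivatives, natural ends
  vapply(uout, function(t) {
    k <- max(1, min(n - 1, findInterval(t, u)))
    dl <- t - u[k]; dr <- u[k + 1] - t
    (m[k] * dr^3 + m[k + 1] * dl^3) / (6 * h[k]) +
      (y[k] / h[k] - m[k] * h[k] / 6) * dr +
      (y[k + 1] / h[k] - m[k + 1] * h[k] / 6) * dl
  }, 0)
}

# random smooth fiber for property tests
random_smooth_fiber <- function(seed, n_controls = 6, spp = 8) {
  withr::with_seed(seed, {
    step <- matrix(rnorm(3 * n_controls, sd = 4), ncol = 3)
    ctrl <- data.frame(
      x = cumsum(step[, 1] + 10), y = cumsum(step[, 2]),
      z = cumsum(step[, 3]), r = runif(n_controls, 1, 3)
    )
    spline_fiber(ctrl, spp, fiber = paste0("rand_", seed))
  })
}

# two clearly separated straight fibers plus a crossing pair
make_crossing_pair <- function(gap_z = 0.5, r = 1) {
  bind_phantoms(
    fiber_points(c(-5, 5), c(0, 0), c(0, 0), c(r, r), "across"),
    fiber_points(c(0, 0), c(-5, 5), c(gap_z, gap_z), c(r, r), "along")
  )
}
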