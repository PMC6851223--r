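test_that("seed grid: lattice spacing, containment, and enumeration oracle", {
  for (case in list(c(1, 0.1, 0.2), c(1, 0.1, 0.4), c(5, 0.4, 1.1),
                    c(60, 0.75, 3))) {
    R <- case[1]; r <- case[2]; s <- case[3]
    seeds <- triangular_seed_grid(R, r, s)
    expect_equal(nrow(seeds), lattice_count_oracle(R, s))
    expect_true(all(sqrt(seeds$u^2 + seeds$v^2) <= R * (1 + 1e-8)))
    if (nrow(seeds) > 1) {
      dmin <- min(dist(cbind(seeds$u, seeds$v)))
      expect_gte(dmin, s * (1 - 1e-9))
    }
  }
  expect_error(triangular_seed_grid(1, 2, 0.5),
               class = "fibrecup_validation_error")
})

test_that("seed count is monotone in spacing and reference radius", {
  counts_s <- vapply(seq(0.2, 2, by = 0.15),
                     function(s) nrow(triangular_seed_grid(2, 0.05, s)), 0L)
  expect_true(all(diff(counts_s) <= 0))
  counts_R <- vapply(seq(0.5, 5, by = 0.25),
                     function(R) nrow(triangular_seed_grid(R, 0.05, 0.4)), 0L)
  expect_true(all(diff(counts_R) >= 0))
})

test_that("boundary seeds are not lost to floating-point jitter", {
  base <- nrow(triangular_seed_grid(60, 0.75, 3))
  expect_equal(nrow(triangular_seed_grid(60 * (1 + 1e-7), 0.75, 3)), base)
  expect_equal(nrow(triangular_seed_grid(60 * (1 - 1e-7), 0.75, 3)), base)
})

test_that("frames are constant on straight fibers and rotate with the tangent", {
  straight <- parametric_fiber("t", "2*t", "0.5*t", "1", 0, 10, 20)
  fr <- transport_frames(straight)
  for (col in c("tx", "ty", "tz", "ux", "uy", "uz", "vx", "vy", "vz")) {
    expect_lt(diff(range(fr[[col]])), 1e-12)
  }

  # planar quarter circle in the xy-plane: the in-plane normal turns 90
  # degrees in total while the out-of-plane component stays fixed
  qc <- parametric_fiber("10*cos(t)", "10*sin(t)", "0", "1", 0, pi / 2, 40)
  fr <- transport_frames(qc)
  n <- nrow(fr)
  u_first <- c(fr$ux[1], fr$uy[1], fr$uz[1])
  u_last <- c(fr$ux[n], fr$uy[n], fr$uz[n])
  # the normals turn by exactly the angle between the end tangents
  # (close to 90 degrees; the one-sided end tangents shave half a step each)
  turn <- acos(fr$tx[1] * fr$tx[n] + fr$ty[1] * fr$ty[n])
  expect_equal(turn, pi / 2, tolerance = 0.05)
  expect_equal(u_last, rodrigues_rotate(u_first, c(0, 0, 1), turn),
               tolerance = 1e-9)
  expect_lt(diff(range(abs(fr$uz))), 1e-9)
})

test_that("transported frames stay orthonormal on random smooth fibers", {
  worst <- 0
  for (seed in 1:100) {
    fr <- transport_frames(random_smooth_fiber(seed))
    TT <- as.matrix(fr[, c("tx", "ty", "tz")])
    U <- as.matrix(fr[, c("ux", "uy", "uz")])
    V <- as.matrix(fr[, c("vx", "vy", "vz")])
    err <- max(
      abs(rowSums(TT^2) - 1), abs(rowSums(U^2) - 1), abs(rowSums(V^2) - 1),
      abs(rowSums(TT * U)), abs(rowSums(TT * V)), abs(rowSums(U * V))
    )
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-6)
})

test_that("straight cylinder fills as parallel fibers at the grid spacing", {
  cyl <- fiber_points(c(0, 50, 100), c(0, 0, 0), c(0, 0, 0), c(5, 5, 5), "cyl")
  ch <- fill_bundle(cyl, r_fiber = 0.4, spacing = 1)
  expect_equal(n_fibers(ch), nrow(triangular_seed_grid(5, 0.4, 1)))
  # each child keeps constant (y, z): parallel straight fibers
  spread <- ch |>
    dplyr::group_by(fiber) |>
    dplyr::summarise(dy = diff(range(y)), dz = diff(range(z)),
                     .groups = "drop")
  expect_lt(max(spread$dy, spread$dz), 1e-9)
  # minimum inter-axis distance equals the spacing (analytic for parallels)
  axes <- ch[ch$point == 1, ]
  expect_equal(min(dist(cbind(axes$y, axes$z))), 1, tolerance = 1e-9)
  expect_true(all(ch$r == 0.4))
})

test_that("widening envelopes scale the child separations proportionally", {
  cone <- fiber_points(c(0, 40, 80), c(0, 0, 0), c(0, 0, 0), c(4, 6, 8), "cone")
  ch <- fill_bundle(cone, r_fiber = 0.3, spacing = 1)
  narrow <- ch[ch$point == 1, ]
  wide <- ch[ch$point == 3, ]
  d_narrow <- as.matrix(dist(cbind(narrow$y, narrow$z)))
  d_wide <- as.matrix(dist(cbind(wide$y, wide$z)))
  expect_equal(d_wide, 2 * d_narrow, tolerance = 1e-9)
})

test_that("when no lattice seed fits, one child runs along the axis", {
  thin <- fiber_points(c(0, 10), c(0, 0), c(0, 0), c(1, 1), "thin")
  ch <- fill_bundle(thin, r_fiber = 0.4, spacing = 5)
  expect_equal(n_fibers(ch), 1)
  expect_equal(ch$y, c(0, 0))
  expect_equal(ch$z, c(0, 0))
})

test_that("filling warns when the spacing falls below the fiber diameter", {
  cyl <- fiber_points(c(0, 10), c(0, 0), c(0, 0), c(2, 2), "c")
  expect_warning(fill_bundle(cyl, r_fiber = 0.5, spacing = 0.8),
                 regexp = "diameter")
})

test_that("filling is equivariant under rigid transforms", {
  env <- parametric_fiber("30*sin(t)", "30*cos(t)", "8*t", "3+t/4", 0, 3, 24)
  axis <- c(0.3, -1, 0.5); ang <- 0.8; off <- c(5, -2, 9); piv <- c(1, 2, 3)
  a <- fill_bundle(env, 0.5, 1.5) |>
    rotate_fibers(axis, ang, pivot = piv) |>
    translate_fibers(off)
  b <- env |>
    rotate_fibers(axis, ang, pivot = piv) |>
    translate_fibers(off) |>
    fill_bundle(0.5, 1.5)
  expect_equal(a$x, b$x, tolerance = 1e-6)
  expect_equal(a$y, b$y, tolerance = 1e-6)
  expect_equal(a$z, b$z, tolerance = 1e-6)
})

test_that("children stay inside the locally scaled envelope", {
  env <- parametric_fiber("20*t", "5*sin(t)", "0", "4+t", 0, 5, 30)
  ch <- fill_bundle(env, 0.5, 1.2)
  fr <- transport_frames(env)
  R_ref <- min(env$r[env$r > 0])
  # seed centers lie within R_ref of the axis, so at data point j the child
  # centers lie within R_j = R_ref * scale_j
  for (j in c(1, 10, 20, 31)) {
    pts <- ch[ch$point == j, ]
    d <- sqrt((pts$x - fr$ox[j])^2 + (pts$y - fr$oy[j])^2 +
                (pts$z - fr$oz[j])^2)
    expect_true(all(d <= env$r[j] * (1 + 1e-9)))
    expect_gte(min(env$r) / R_ref, 1)  # envelope never narrower than R_ref
  }
})
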