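# helper: a volume with homogeneous columns of given direction/inclination
# and tissue depth (in voxels), built directly, bypassing voxelize()
homogeneous_volume <- function(phi, alpha, n_tissue, nz = max(n_tissue),
                               voxel_size = 1) {
  n <- length(phi)
  orient <- array(NA_real_, c(n, 1, nz, 3))
  tissue <- array(FALSE, c(n, 1, nz))
  for (k in seq_len(n)) {
    if (n_tissue[k] > 0) {
      orient[k, 1, seq_len(n_tissue[k]), 1] <- cos(phi[k]) * cos(alpha[k])
      orient[k, 1, seq_len(n_tissue[k]), 2] <- sin(phi[k]) * cos(alpha[k])
      orient[k, 1, seq_len(n_tissue[k]), 3] <- sin(alpha[k])
      tissue[k, 1, seq_len(n_tissue[k])] <- TRUE
    }
  }
  structure(
    list(dim = c(n, 1L, nz), origin = c(0, 0, 0), voxel_size = voxel_size,
         orientation = orient, tissue = tissue,
         dist = array(ifelse(tissue, 0, Inf), c(n, 1, nz))),
    class = "voxel_volume"
  )
}

test_that("voxelization recovers capsule geometry and orientations", {
  fb <- fiber_points(c(-20, 20), c(0, 0), c(0, 0), c(2, 2), "f")
  vol <- voxelize(fb, c(-5, 5, -4, 4, -4, 4), 1)
  expect_equal(vol$dim, c(10L, 8L, 8L))
  # every x-slice cuts a disc of radius 2 (area 4 pi ~ 12.6 voxel centers)
  per_slice <- apply(vol$tissue, 1, sum)
  expect_true(all(per_slice >= 9 & per_slice <= 16))
  o1 <- vol$orientation[, , , 1]
  expect_true(all(o1[vol$tissue] == 1))
  expect_error(voxelize(fb, c(-5, 5, -4, 4, -4, 4), 0),
               class = "fibrecup_validation_error")
})

test_that("regions without fibers stay background", {
  fb <- fiber_points(c(100, 120), c(100, 100), c(0, 0), c(1, 1), "far")
  vol <- voxelize(fb, c(-5, 5, -5, 5, -2, 2), 1)
  expect_false(any(vol$tissue))
})

test_that("crossing fibers resolve by the nearest-axis rule", {
  ph <- bind_phantoms(
    fiber_points(c(-20, 20), c(0, 0), c(-1.2, -1.2), c(2, 2), "fx"),
    fiber_points(c(0, 0), c(-20, 20), c(1.2, 1.2), c(2, 2), "fy")
  )
  vol <- voxelize(ph, c(-6, 6, -6, 6, -3, 3), 1)
  # brute-force point-in-capsule oracle over every voxel center
  centers <- expand.grid(
    x = seq(-6 + 0.5, 6 - 0.5, by = 1),
    y = seq(-6 + 0.5, 6 - 0.5, by = 1),
    z = seq(-3 + 0.5, 3 - 0.5, by = 1)
  )
  seg_dist <- function(p, a, b) {
    d <- b - a
    tt <- min(1, max(0, sum((p - a) * d) / sum(d * d)))
    sqrt(sum((p - a - tt * d)^2))
  }
  for (k in seq_len(nrow(centers))) {
    p <- as.numeric(centers[k, ])
    dx <- seg_dist(p, c(-20, 0, -1.2), c(20, 0, -1.2))
    dy <- seg_dist(p, c(0, -20, 1.2), c(0, 20, 1.2))
    idx <- cbind(centers$x[k] + 6.5, centers$y[k] + 6.5, centers$z[k] + 3.5)
    expect_equal(vol$tissue[idx], dx < 2 || dy < 2)
    if (dx < 2 || dy < 2) {
      want <- if (dx <= dy) c(1, 0, 0) else c(0, 1, 0)
      got <- c(
        vol$orientation[idx[1], idx[2], idx[3], 1],
        vol$orientation[idx[1], idx[2], idx[3], 2],
        vol$orientation[idx[1], idx[2], idx[3], 3]
      )
      expect_equal(abs(got), want, tolerance = 1e-12)
    }
  }
})

test_that("background columns give the crossed-polars baseline I0/2", {
  vol <- homogeneous_volume(0, 0, n_tissue = 0, nz = 10)
  params <- optics_params(absorption = 0)
  st <- simulate_measurement(vol, params, check_stokes = TRUE)
  expect_equal(as.numeric(st), rep(params$I0 / 2, length(params$angles)),
               tolerance = 1e-12)
})

test_that("vertical fibers produce a flat signal (zero retardance)", {
  vol <- homogeneous_volume(0, pi / 2, n_tissue = 10)
  st <- simulate_measurement(vol, optics_params(absorption = 0))
  expect_lt(diff(range(st)), 1e-9 * optics_params()$I0)
})

test_that("the Mueller chain matches the closed form on homogeneous columns", {
  params <- optics_params()
  lam <- params$wavelength / 1000
  n_cases <- 250
  withr::with_seed(101, {
    phi <- runif(n_cases, 0, pi)
    alpha <- runif(n_cases, 0, pi / 2)
    depth <- sample(10:60, n_cases, replace = TRUE)
  })
  vol <- homogeneous_volume(phi, alpha, depth)
  st <- simulate_measurement(vol, params, check_stokes = TRUE)
  att <- exp(-params$absorption * depth * vol$voxel_size / 1000)
  worst <- 0
  for (k in seq_len(n_cases)) {
    delta_tot <- 2 * pi * depth[k] * vol$voxel_size / lam *
      params$birefringence * cos(alpha[k])^2
    want <- pli_signal(params$angles, phi[k], delta_tot, params$I0 * att[k])
    got <- as.numeric(st[k, 1, ])
    worst <- max(worst, max(abs(got - want) / abs(want)))
  }
  expect_lt(worst, 1e-9)
})

test_that("blur preserves the mean and downsampling needs integer factors", {
  flat <- structure(array(7, c(40, 40, 2)), angles = c(0, pi / 4),
                    pixel_size = 1, params = NULL, class = "pli_stack")
  params <- optics_params(pixel_size = 20)
  small <- downsample_blur(flat, params)
  expect_equal(dim(small), c(2, 2, 2))
  expect_equal(as.numeric(small), rep(7, 8), tolerance = 1e-9)

  withr::with_seed(5, {
    img <- structure(array(runif(40 * 40, 0, 100), c(40, 40, 1)),
                     angles = 0, pixel_size = 1, params = NULL,
                     class = "pli_stack")
  })
  out <- downsample_blur(img, params)
  expect_equal(mean(out), mean(img), tolerance = 1e-6)

  expect_error(downsample_blur(flat, optics_params(pixel_size = 7.5)),
               class = "fibrecup_validation_error")
})

test_that("noise is unbiased, seeded, and optional", {
  st <- structure(array(13000, c(100, 100, 1)), angles = 0, pixel_size = 20,
                  params = NULL, class = "pli_stack")
  params <- optics_params(noise = TRUE)
  a <- add_noise(st, params, seed = 9)
  b <- add_noise(st, params, seed = 9)
  expect_identical(as.numeric(a), as.numeric(b))
  c2 <- add_noise(st, params, seed = 10)
  expect_false(identical(as.numeric(a), as.numeric(c2)))
  # 10^4 replicate pixels: sample mean within 3 standard errors
  se <- sqrt(params$noise_gain * 13000 / length(st))
  expect_lt(abs(mean(a) - 13000), 3 * se)
  off <- add_noise(st, optics_params(noise = FALSE), seed = 1)
  expect_identical(as.numeric(off), as.numeric(st))
  expect_error(add_noise(st, params), class = "fibrecup_validation_error")
})

test_that("orientation recovery inverts the closed form", {
  params <- optics_params(absorption = 0)
  phi_true <- 75 * pi / 180
  vol <- homogeneous_volume(phi_true, 0, n_tissue = 60)
  st <- simulate_measurement(vol, params)
  map <- recover_orientation(st, params)
  expect_true(map$valid[1])
  expect_lt(abs(map$phi[1] - phi_true), 1e-4)
  expect_lt(abs(map$alpha[1] - 0), 1e-3)

  # vertical fibers: no modulation, direction undefined
  volv <- homogeneous_volume(0.3, pi / 2, n_tissue = 60)
  mapv <- recover_orientation(simulate_measurement(volv, params), params)
  expect_false(mapv$valid[1])
  expect_error(
    recover_orientation(
      structure(array(1, c(2, 2, 2)), angles = c(0, 1), pixel_size = 1,
                params = NULL, class = "pli_stack"),
      params
    ),
    class = "fibrecup_validation_error"
  )
})

test_that("a symmetric equal crossing recovers the bisector direction", {
  params <- optics_params(absorption = 0)
  gamma <- 30 * pi / 180
  # two equal stacked layers at +/- gamma: 30 voxels each
  orient <- array(NA_real_, c(1, 1, 60, 3))
  orient[1, 1, 1:30, ] <- rep(c(cos(gamma), sin(gamma), 0), each = 30)
  orient[1, 1, 31:60, ] <- rep(c(cos(-gamma), sin(-gamma), 0), each = 30)
  vol <- structure(
    list(dim = c(1L, 1L, 60L), origin = c(0, 0, 0), voxel_size = 1,
         orientation = orient, tissue = array(TRUE, c(1, 1, 60)),
         dist = array(0, c(1, 1, 60))),
    class = "voxel_volume"
  )
  map <- recover_orientation(simulate_measurement(vol, params), params)
  err <- abs(map$phi[1] - 0)
  err <- min(err, pi - err)
  expect_lt(err * 180 / pi, 2)
})

test_that("orientation colors are antipodal and continuous", {
  expect_equal(as.numeric(orientation_to_color(c(0, 0, 1), "rgb")),
               c(0, 0, 1))
  expect_equal(as.numeric(orientation_to_color(c(0, 0, -3), "rgb")),
               c(0, 0, 1))
  withr::with_seed(3, {
    for (k in 1:100) {
      v <- rnorm(3)
      for (mode in c("rgb", "hsv")) {
        expect_equal(orientation_to_color(v, mode),
                     orientation_to_color(-v, mode), tolerance = 1e-12)
      }
    }
  })
  # hue sweep: in-plane directions over [0, pi), colors continuous across
  # the phi = 0 / pi boundary
  phis <- seq(0, pi, length.out = 361)[-361]
  cols <- orientation_to_color(cbind(cos(phis), sin(phis), 0), "hsv")
  jumps <- sqrt(rowSums((cols[-1, ] - cols[-nrow(cols), ])^2))
  wrap <- sqrt(sum((cols[1, ] - cols[nrow(cols), ])^2))
  expect_lt(max(jumps, wrap), 0.05)
  expect_error(orientation_to_color(c(0, 0, 0)),
               class = "fibrecup_validation_error")
})

test_that("end-to-end: a straight filled bundle is recovered at its angles", {
  # the inclination is checked at a tilted orientation: the inverse map
  # alpha = acos(sqrt(.)) is ill-conditioned at alpha = 0, where sub-percent
  # retardance bias from averaging over columns blows up into degrees
  cases <- list(
    inplane = list(phi = 30 * pi / 180, alpha = 0, check_alpha = FALSE),
    tilted = list(phi = 120 * pi / 180, alpha = 30 * pi / 180,
                  check_alpha = TRUE)
  )
  for (cs in cases) {
    dirv <- c(cos(cs$phi) * cos(cs$alpha), sin(cs$phi) * cos(cs$alpha),
              sin(cs$alpha))
    env <- parametric_fiber(
      sprintf("%.12f*t", dirv[1]), sprintf("%.12f*t", dirv[2]),
      sprintf("%.12f*t", dirv[3]), "40", -90, 90, 40, fiber = "bundle"
    )
    ch <- fill_bundle(env, r_fiber = 1.4, spacing = 2.8)
    vol <- voxelize(ch, c(-20, 20, -20, 20, -20, 20), 1)
    fill_fraction <- mean(vol$tissue)
    expect_gt(fill_fraction, 0.75)
    params <- optics_params(pixel_size = 20, thickness = 40 * fill_fraction,
                            noise = FALSE)
    stack <- simulate_measurement(vol, params) |> downsample_blur(params)
    map <- recover_orientation(stack, params)
    expect_true(all(map$valid))
    err_phi <- abs(map$phi - cs$phi)
    err_phi <- pmin(err_phi, pi - err_phi)
    expect_lt(stats::median(err_phi) * 180 / pi, 1)
    if (cs$check_alpha) {
      expect_lt(stats::median(abs(map$alpha - cs$alpha)) * 180 / pi, 3)
    }
  }
})

test_that("with noise, more polarizer angles tighten the direction estimate", {
  phi_true <- 50 * pi / 180
  vol <- homogeneous_volume(rep(phi_true, 400), rep(0, 400), rep(60, 400))
  err_for <- function(n_angles, seed) {
    params <- optics_params(
      angles = seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)],
      noise = TRUE
    )
    st <- simulate_measurement(vol, params) |>
      add_noise(params, seed = seed)
    map <- recover_orientation(st, params)
    e <- abs(map$phi - phi_true)
    stats::median(pmin(e, pi - e), na.rm = TRUE)
  }
  expect_lt(err_for(36, seed = 21), err_for(6, seed = 21))
})
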