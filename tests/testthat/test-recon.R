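test_that("U and s' match their closed forms and reject r >= D", {
  expect_equal(compute_U(0, 123, 45, 4), 1)
  expect_equal(compute_U(2, 0, 90, 4), 1.5)
  expect_equal(compute_U(2, 30, 60, 4), 1.25)   # sin 30 deg = 1/2
  expect_equal(compute_sprime(0, 10, 200, 4), 0)
  expect_equal(compute_sprime(0.7, 30, 30, 4), 0.7)   # beta == phi
  expect_equal(compute_sprime(0.5, 0, 30, 1), sqrt(3) / 5, tolerance = 1e-14)
  expect_error(compute_U(4, 0, 0, 4), "< D")
  expect_error(compute_sprime(-0.1, 0, 0, 4), ">= 0")
})

test_that("quarter-turn trig identities hold in the angle handling", {
  set.seed(5)
  a <- runif(1e4, 0, 360)
  expect_close(sind(a + 90), cosd(a), 1e-12)
  expect_close(cosd(a + 90), -sind(a), 1e-12)
  expect_close(sind(a + 180), -sind(a), 1e-12)
  expect_close(cosd(a + 180), -cosd(a), 1e-12)
  expect_close(sind(a + 270), -cosd(a), 1e-12)
  expect_close(cosd(a + 270), sind(a), 1e-12)
})

test_that("(U, s') sharing relations hold across the symmetry orbit", {
  set.seed(6)
  n <- 1e4
  D <- runif(n, 1, 10)
  r <- runif(n) * 0.99 * D
  phi <- runif(n, 0, 360)
  beta <- runif(n, 0, 360)
  U <- compute_U(r, phi, beta, D)
  sp <- compute_sprime(r, phi, beta, D)
  for (q in 1:3) {
    # simultaneous quarter-turn of point and view leaves (U, s') unchanged
    expect_close(U, compute_U(r, phi + 90 * q, beta + 90 * q, D), 1e-12)
    expect_close(sp, compute_sprime(r, phi + 90 * q, beta + 90 * q, D), 1e-12)
  }
  # cross-quadrant closed forms from the already-computed sin/cos
  rs <- r * sind(beta - phi)
  rc <- r * cosd(beta - phi)
  expect_close(compute_U(r, phi + 90, beta, D), (D - rc) / D, 1e-12)
  expect_close(compute_sprime(r, phi + 90, beta, D), D * rs / (D - rc), 1e-12)
  expect_close(compute_U(r, phi + 180, beta, D), (D - rs) / D, 1e-12)
  expect_close(compute_sprime(r, phi + 180, beta, D), -D * rc / (D - rs), 1e-12)
  expect_close(compute_U(r, phi + 270, beta, D), (D + rc) / D, 1e-12)
  expect_close(compute_sprime(r, phi + 270, beta, D), -D * rs / (D + rc), 1e-12)
  # and the rotated-spot chain: the phi+90 spot at view beta equals the
  # phi+180 spot at beta+90, the phi+270 spot at beta+180, the original
  # spot at beta+270
  U1 <- compute_U(r, phi + 90, beta, D)
  s1 <- compute_sprime(r, phi + 90, beta, D)
  expect_close(U1, compute_U(r, phi + 180, beta + 90, D), 1e-12)
  expect_close(U1, compute_U(r, phi + 270, beta + 180, D), 1e-12)
  expect_close(U1, compute_U(r, phi, beta + 270, D), 1e-12)
  expect_close(s1, compute_sprime(r, phi + 180, beta + 90, D), 1e-12)
  expect_close(s1, compute_sprime(r, phi + 270, beta + 180, D), 1e-12)
  expect_close(s1, compute_sprime(r, phi, beta + 270, D), 1e-12)
})

test_that("cosine pre-weight scales columns by D / sqrt(D^2 + s^2)", {
  g <- fan_geometry(4, 8, 9, 1)
  sino <- sinogram(matrix(1, 8, 9), g)
  w <- cos_preweight(sino)$values
  s <- detector_coords(g)
  expect_equal(w[1, s == 0], 1)
  expect_equal(w[1, abs(s - 4) < 1e-9], 1 / sqrt(2))
  expect_true(all(diff(w[1, order(abs(s))]) <= 0))
})

test_that("ramp filter is linear, reproduces the kernel and suppresses DC", {
  g <- fan_geometry(4, 4, 65, 0.02)
  zero <- sinogram(matrix(0, 4, 65), g)
  expect_equal(ramp_filter(zero)$values, matrix(0, 4, 65))
  # impulse response: the discrete Ram-Lak kernel, brute-forced from its
  # definition h(0) = 1/(4 ds^2), h odd = -1/(pi^2 m^2 ds^2), h even = 0
  imp <- matrix(0, 4, 65); imp[1, 33] <- 1
  got <- ramp_filter(sinogram(imp, g))$values[1, ]
  m <- (1:65) - 33
  ds <- 0.02
  h <- ifelse(m == 0, 1 / (4 * ds^2),
              ifelse(m %% 2 != 0, -1 / (pi^2 * m^2 * ds^2), 0))
  expect_equal(got, h * ds, tolerance = 1e-12)
  # linearity
  set.seed(8)
  A <- matrix(rnorm(4 * 65), 4, 65); B <- matrix(rnorm(4 * 65), 4, 65)
  expect_equal(ramp_filter(sinogram(A + 2 * B, g))$values,
               ramp_filter(sinogram(A, g))$values +
                 2 * ramp_filter(sinogram(B, g))$values,
               tolerance = 1e-10)
  # DC suppression: a constant row filters to near zero relative to the
  # kernel peak response 1/(4 ds). The center bin sees lags to +/-(nb-1)/2,
  # so the truncated-tail residue is bounded by 16 / (pi^2 (nb - 1))
  const <- ramp_filter(sinogram(matrix(1, 4, 65), g))$values[1, 33]
  expect_lt(abs(const) / (1 / (4 * ds)), 16 / (pi^2 * 64))
  expect_error(ramp_filter(sinogram(matrix(1, 4, 2), fan_geometry(4, 4, 2, 1))),
               "n_bins >= 3")
})

test_that("symmetry orbits partition the grid into exact quarter-turn quadruples", {
  # n = 2: one orbit of 4 pixels sharing one radius
  o2 <- build_symmetry_orbits(2, 0.5)
  expect_equal(nrow(o2$members), 1)
  expect_setequal(as.vector(o2$members), 1:4)
  expect_equal(o2$r, sqrt(2) / 4)
  # n = 3: two quadruples plus the singleton center
  o3 <- build_symmetry_orbits(3, 1)
  expect_equal(nrow(o3$members), 3)
  expect_equal(sum(o3$singleton), 1)
  expect_setequal(as.vector(o3$members[!o3$singleton, ]), setdiff(1:9, 5))
  expect_equal(unname(o3$members[o3$singleton, 1]), 5)
  for (n in c(4, 5, 8, 9)) {
    o <- build_symmetry_orbits(n, 2 / n)
    cc <- if (n %% 2 == 1) 1 else 0
    expect_equal(nrow(o$members), (n^2 - cc) / 4 + cc)
    # every pixel in exactly one orbit
    all_members <- c(o$members[!o$singleton, ],
                     o$members[o$singleton, 1])
    expect_setequal(all_members, seq_len(n^2))
    expect_equal(length(all_members), n^2)
    # members are exact 90-degree rotations sharing r; angles step by 90
    pc <- pixel_centers(n, 2 / n)
    x <- as.vector(pc$x); y <- as.vector(pc$y)
    for (orb in which(!o$singleton)) {
      ids <- o$members[orb, ]
      rr <- sqrt(x[ids]^2 + y[ids]^2)
      expect_lt(max(abs(rr - o$r[orb])) / o$r[orb], 1e-12)
      for (m in 1:3) {
        # CCW rotation: (x, y) -> (-y, x)
        expect_identical(x[ids[m + 1]], -y[ids[m]])
        expect_identical(y[ids[m + 1]], x[ids[m]])
      }
      ang <- atan2(y[ids], x[ids]) * 180 / pi
      expect_equal(sort(((ang - ang[1]) %% 360)), c(0, 90, 180, 270))
    }
  }
})

test_that("single-pixel back-projection reduces to the central-ray sum", {
  g <- fan_geometry(4, 12, 9, 0.5)
  set.seed(9)
  q <- sinogram(matrix(rnorm(12 * 9), 12, 9), g)
  got <- backproject_naive(q, 1, 0.1)
  expect_equal(got$values[1, 1], (2 * pi / 12) * sum(q$values[, 5]))
})

test_that("symmetry back-projection equals the naive oracle with 4x fewer geometry pairs", {
  sp <- random_phantom(3)
  g <- make_geom(1, 72, 129)
  q <- ramp_filter(cos_preweight(project_analytic(sp, g)))
  for (n in c(16, 17)) {
    cn <- new_op_counter(); cs <- new_op_counter()
    a <- backproject_naive(q, n, 2 / n, cn)
    b <- backproject_symmetry(q, n, 2 / n, cs)
    expect_lt(max(abs(a$values - b$values)) / max(abs(a$values)), 1e-6)
    # regrouped identical summands: totals agree to float tolerance
    expect_lt(abs(sum(a$values) - sum(b$values)) / sum(abs(a$values)), 1e-12)
    if (n %% 2 == 0) {
      expect_identical(cs$geom_evals / cn$geom_evals, 0.25)
      expect_identical(cs$trig_evals / cn$trig_evals, 1 / 16)
    }
  }
  expect_error(backproject_symmetry(
    sinogram(matrix(0, 6, 129), fan_geometry(4, 6, 129, 0.02)), 8, 0.1),
    "divisible by 4")
})

test_that("back-projectors reject a grid that reaches the source circle", {
  g <- fan_geometry(1, 8, 9, 0.3)
  q <- sinogram(matrix(0, 8, 9), g)
  expect_error(backproject_naive(q, 64, 0.1), "incompatible")
  expect_error(backproject_symmetry(q, 64, 0.1), "incompatible")
})

test_that("back-projection is rotationally equivariant over quarter turns", {
  sp <- random_phantom(4)
  g <- make_geom(1, 72, 129)
  q <- ramp_filter(cos_preweight(project_analytic(sp, g)))
  V4 <- g$n_views / 4
  shifted <- sinogram(q$values[c((g$n_views - V4 + 1):g$n_views,
                                 1:(g$n_views - V4)), ], g)
  for (method in c(backproject_naive, backproject_symmetry)) {
    a <- method(shifted, 16, 2 / 16)
    b <- rotate_grid_90(method(q, 16, 2 / 16))
    expect_lt(max(abs(a$values - b$values)) / max(abs(b$values)), 1e-10)
  }
})

test_that("reconstruct pipelines agree across methods and propagate zeros", {
  g <- make_geom(1, 40, 65)
  zero <- sinogram(matrix(0, 40, 65), g)
  expect_equal(reconstruct(zero, 8, 0.25, "naive")$image$values, matrix(0, 8, 8))
  expect_equal(reconstruct(zero, 8, 0.25, "symmetry")$image$values, matrix(0, 8, 8))
  for (seed in 1:5) {
    sino <- project_analytic(random_phantom(seed), g)
    a <- reconstruct(sino, 12, 2 / 12, "naive")$image$values
    b <- reconstruct(sino, 12, 2 / 12, "symmetry")$image$values
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-6)
  }
})
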