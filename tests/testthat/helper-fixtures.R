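# shared fixtures: all inputs are generated in code at test time

# uniform disk phantom of radius R and value v
disk_phantom <- function(R = 0.5, v = 1) {
  phantom_spec(list(ellipse(0, 0, R, R, 0, v)), R)
}

# geometry whose detector covers the fan shadow of a bounding radius with
# 10% margin (the package-wide study condition)
make_geom <- function(R0, n_views, n_bins, D = 4 * R0) {
  shadow <- D * R0 / sqrt(D^2 - R0^2)
  fan_geometry(D, n_views, n_bins, 2 * 1.1 * shadow / n_bins)
}

# random multi-ellipse phantom inside a unit disk, deterministic given seed
random_phantom <- function(seed, n_ellipses = 3) {
  set.seed(seed)
  ells <- lapply(seq_len(n_ellipses), function(k) {
    a <- runif(1, 0.05, 0.3)
    b <- runif(1, 0.05, 0.3)
    rho <- runif(1, 0, 0.9 - max(a, b))
    ang <- runif(1, 0, 2 * pi)
    ellipse(rho * cos(ang), rho * sin(ang), a, b,
            runif(1, 0, 180), runif(1, 0.2, 1))
  })
  phantom_spec(ells, 1)
}

# |a - b| relative to max(|a|, |b|, floor)
rel_diff <- function(a, b, floor = 1) {
  abs(a - b) / pmax(abs(a), abs(b), floor)
}

expect_close <- function(a, b, tol, floor = 1) {
  expect_true(all(rel_diff(a, b, floor) <= tol),
              label = sprintf("max rel diff %.3g <= %.3g",
                              max(rel_diff(a, b, floor)), tol))
}

sind <- function(x) sin(x * pi / 180)
cosd <- function(x) cos(x * pi / 180)
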