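#' Analytic fan-beam projection of an ellipse phantom
#'
#' Computes the sinogram exactly: each entry is the sum over ellipses of
#' (chord length of the ray through the ellipse) times the ellipse value,
#' using the closed-form line/ellipse intersection. This is the reference
#' data source for the reconstruction chain and the oracle for the numeric
#' projector.
#'
#' @param spec A [phantom_spec()].
#' @param geom A [fan_geometry()]. The detector must cover the fan shadow of
#'   the bounding disk at all views and `D` must exceed the bounding radius.
#' @return A [sinogram()].
#' @export
#' @examples
#' g <- fan_geometry(D = 4, n_views = 90, n_bins = 129, bin_spacing = 2.2 / 128)
#' s <- project_analytic(default_head_phantom(), g)
project_analytic <- function(spec, geom) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(geom, "fan_geometry"))
  check_field_of_view(spec$bounding_radius, geom)
  betas <- view_angles_deg(geom) * pi / 180
  s <- detector_coords(geom)
  vals <- matrix(0, geom$n_views, geom$n_bins)
  D <- geom$D
  for (k in seq_len(geom$n_views)) {
    b <- betas[k]
    src <- c(-D * sin(b), D * cos(b))
    dx <- s * cos(b) - src[1]
    dy <- s * sin(b) - src[2]
    nrm <- sqrt(dx^2 + dy^2)
    dx <- dx / nrm; dy <- dy / nrm
    row <- numeric(geom$n_bins)
    for (e in spec$ellipses) {
      row <- row + e$value *
        chord_lengths(src[1], src[2], dx, dy, e)
    }
    vals[k, ] <- row
  }
  sinogram(vals, geom)
}

# chord length of rays (p0 + t * d, unit d) through an ellipse; vectorized
# over the direction components.
chord_lengths <- function(px, py, dx, dy, e) {
  th <- -e$theta_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  # ray origin and direction in the ellipse frame
  ox <- px - e$cx; oy <- py - e$cy
  oxr <- ox * ct - oy * st
  oyr <- ox * st + oy * ct
  dxr <- dx * ct - dy * st
  dyr <- dx * st + dy * ct
  A <- (dxr / e$a)^2 + (dyr / e$b)^2
  B <- 2 * (oxr * dxr / e$a^2 + oyr * dyr / e$b^2)
  C <- (oxr / e$a)^2 + (oyr / e$b)^2 - 1
  disc <- B^2 - 4 * A * C
  len <- numeric(length(dxr))
  hit <- disc > 0
  len[hit] <- sqrt(disc[hit]) / A[hit]
  len
}

check_field_of_view <- function(radius, geom) {
  if (radius >= geom$D)
    stop("object bounding radius (", radius,
         ") must be smaller than source distance D = ", geom$D)
  # fan shadow of the bounding disk on the virtual detector
  shadow <- geom$D * radius / sqrt(geom$D^2 - radius^2)
  half_width <- geom$n_bins * geom$bin_spacing / 2
  if (half_width < shadow)
    stop("detector half-width ", half_width,
         " does not cover the object's fan shadow ", signif(shadow, 6))
  invisible(TRUE)
}

#' Numeric fan-beam projection of a pixel grid
#'
#' Approximates line integrals by sampling the grid with bilinear
#' interpolation at spacing `step` along each ray. Converges to
#' [project_analytic()] of the generating phantom as `step -> 0` and the
#' raster resolution grows.
#'
#' @param grid An [image_grid()].
#' @param geom A [fan_geometry()].
#' @param step Sampling step along the ray (> 0); defaults to half a pixel.
#' @return A [sinogram()].
#' @export
project_numeric <- function(grid, geom, step = grid$pixel_size / 2) {
  stopifnot(inherits(grid, "image_grid"), inherits(geom, "fan_geometry"))
  if (!is.numeric(step) || step <= 0) stop("'step' must be > 0")
  betas <- view_angles_deg(geom) * pi / 180
  s <- detector_coords(geom)
  D <- geom$D
  half_diag <- grid$n * grid$pixel_size / sqrt(2)  # circumscribed radius
  t_seq <- seq(max(D - half_diag, 0), D + half_diag, by = step)
  vals <- matrix(0, geom$n_views, geom$n_bins)
  for (k in seq_len(geom$n_views)) {
    b <- betas[k]
    src <- c(-D * sin(b), D * cos(b))
    dx <- s * cos(b) - src[1]
    dy <- s * sin(b) - src[2]
    nrm <- sqrt(dx^2 + dy^2)
    dx <- dx / nrm; dy <- dy / nrm
    # sample all bins x all depths at once
    px <- outer(dx, t_seq) + src[1]
    py <- outer(dy, t_seq) + src[2]
    samp <- bilinear_sample(grid, px, py)
    vals[k, ] <- rowSums(samp) * step
  }
  sinogram(vals, geom)
}

# bilinear interpolation on an image_grid, zero outside the grid;
# x, y may be vectors or matrices.
bilinear_sample <- function(grid, x, y) {
  n <- grid$n; ps <- grid$pixel_size
  c0 <- (n + 1) / 2
  jf <- x / ps + c0
  if_ <- c0 - y / ps
  j0 <- floor(jf); i0 <- floor(if_)
  wj <- jf - j0; wi <- if_ - i0
  v <- grid$values
  val_at <- function(i, j) {
    ok <- i >= 1 & i <= n & j >= 1 & j <= n
    out <- numeric(length(i))
    out[ok] <- v[cbind(i[ok], j[ok])]
    out
  }
  out <- (1 - wi) * (1 - wj) * val_at(i0, j0) +
    (1 - wi) * wj * val_at(i0, j0 + 1) +
    wi * (1 - wj) * val_at(i0 + 1, j0) +
    wi * wj * val_at(i0 + 1, j0 + 1)
  dim(out) <- dim(jf)
  out
}

#' Add Gaussian noise to a sinogram
#'
#' Adds i.i.d. zero-mean Gaussian noise with standard deviation `sigma`.
#' Deterministic given `seed`; the caller's RNG state is left untouched.
#'
#' @param sino A [sinogram()].
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return A [sinogram()] with noise added.
#' @export
add_noise <- function(sino, sigma, seed) {
  stopifnot(inherits(sino, "sinogram"))
  if (!is.numeric(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (sigma == 0) return(sino)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  noisy <- sino$values +
    matrix(stats::rnorm(length(sino$values), sd = sigma),
           nrow(sino$values), ncol(sino$values))
  sinogram(noisy, sino$geometry)
}
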