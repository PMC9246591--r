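#' Construct an ellipse record
#'
#' An additive ellipse is the building block of the 2-D phantoms used to
#' exercise the projection/reconstruction chain. All lengths are in the same
#' (arbitrary) physical unit as the grid's `pixel_size` and the geometry's
#' source distance `D`.
#'
#' @param cx,cy Center coordinates.
#' @param a,b Semi-axes; `a` lies along the local x axis before rotation.
#'   Both must be strictly positive.
#' @param theta_deg Counterclockwise rotation of the ellipse, degrees.
#' @param value Additive intensity contributed inside the ellipse
#'   (dimensionless attenuation-like value; may be negative).
#' @return An object of class `"ellipse"`.
#' @export
#' @examples
#' ellipse(0, 0, 1, 0.5, theta_deg = 30, value = 1)
ellipse <- function(cx, cy, a, b, theta_deg = 0, value = 1) {
  stopifnot(is.numeric(cx), is.numeric(cy), is.numeric(a), is.numeric(b),
            is.numeric(theta_deg), is.numeric(value))
  if (!(a > 0) || !(b > 0)) stop("ellipse semi-axes 'a' and 'b' must be > 0")
  if (!is.finite(value)) stop("ellipse 'value' must be finite")
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy),
                 a = as.numeric(a), b = as.numeric(b),
                 theta_deg = as.numeric(theta_deg),
                 value = as.numeric(value)),
            class = "ellipse")
}

#' Construct a phantom specification
#'
#' A phantom is an ordered list of additive ellipses together with a bounding
#' radius; every ellipse must lie entirely inside the disk of that radius
#' centered on the isocenter (checked via center distance plus the larger
#' semi-axis, a sufficient condition).
#'
#' @param ellipses List of [ellipse()] objects.
#' @param bounding_radius Radius of the disk containing the whole object.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(ellipses, bounding_radius) {
  if (!is.list(ellipses) || !all(vapply(ellipses, inherits, TRUE, "ellipse")))
    stop("'ellipses' must be a list of ellipse objects")
  stopifnot(is.numeric(bounding_radius), bounding_radius > 0)
  for (e in ellipses) {
    if (sqrt(e$cx^2 + e$cy^2) + max(e$a, e$b) > bounding_radius + 1e-12)
      stop("ellipse centered at (", e$cx, ", ", e$cy,
           ") extends beyond bounding_radius = ", bounding_radius)
  }
  structure(list(ellipses = ellipses,
                 bounding_radius = as.numeric(bounding_radius)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", length(x$ellipses), "ellipse(s), bounding radius",
      x$bounding_radius, "\n")
  invisible(x)
}

#' Test whether a point lies inside an ellipse
#'
#' @param x,y Point coordinates (vectorized).
#' @param e An [ellipse()].
#' @return Logical vector; `TRUE` where ((x'/a)^2 + (y'/b)^2) <= 1 with
#'   (x', y') the point relative to the center, rotated by `-theta_deg`.
#' @export
point_in_ellipse <- function(x, y, e) {
  stopifnot(inherits(e, "ellipse"))
  th <- -e$theta_deg * pi / 180
  dx <- x - e$cx
  dy <- y - e$cy
  xr <- dx * cos(th) - dy * sin(th)
  yr <- dx * sin(th) + dy * cos(th)
  (xr / e$a)^2 + (yr / e$b)^2 <= 1
}

#' Construct an image grid
#'
#' The grid is an n-by-n matrix of real values with physical pixel size.
#' Pixel `(i, j)` (row i from the top, column j, 1-based) has its center at
#' `x = (j - (n+1)/2) * pixel_size`, `y = ((n+1)/2 - i) * pixel_size`, so the
#' grid is centered on the isocenter and a 90-degree rotation about the
#' center maps pixel centers onto pixel centers exactly (for odd n the center
#' pixel is its own image).
#'
#' @param values n-by-n numeric matrix.
#' @param pixel_size Physical side length of one pixel.
#' @return An object of class `"image_grid"`.
#' @export
image_grid <- function(values, pixel_size) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("image grid must be square")
  if (!all(is.finite(values))) stop("image grid values must be finite")
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  structure(list(values = values, n = nrow(values),
                 pixel_size = as.numeric(pixel_size)),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("image_grid: ", x$n, "x", x$n, " pixels, pixel_size = ", x$pixel_size,
      ", range [", signif(min(x$values), 4), ", ", signif(max(x$values), 4),
      "]\n", sep = "")
  invisible(x)
}

#' Physical coordinates of all pixel centers
#'
#' @param n Grid side, pixels.
#' @param pixel_size Physical pixel size.
#' @return List with matrices `x` and `y` (n-by-n) of pixel-center
#'   coordinates, following the [image_grid()] convention.
#' @export
pixel_centers <- function(n, pixel_size) {
  c0 <- (n + 1) / 2
  j <- matrix(seq_len(n), n, n, byrow = TRUE)
  i <- matrix(seq_len(n), n, n)
  list(x = (j - c0) * pixel_size, y = (c0 - i) * pixel_size)
}

#' Rasterize a phantom onto a centered pixel grid
#'
#' Each pixel value is the sum of ellipse `value`s over the ellipses that
#' contain that pixel's center (pixel-center sampling, no antialiasing: this
#' is the rasterization contract, chosen so that rasterization commutes
#' exactly with 90-degree rotations of the phantom).
#'
#' @param spec A [phantom_spec()].
#' @param n Pixels per side (>= 2).
#' @param pixel_size Physical pixel size (> 0).
#' @return An [image_grid()].
#' @export
rasterize <- function(spec, n, pixel_size) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(n) || n < 2 || n != round(n)) stop("'n' must be an integer >= 2")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("'pixel_size' must be > 0")
  pc <- pixel_centers(n, pixel_size)
  vals <- matrix(0, n, n)
  for (e in spec$ellipses) {
    inside <- point_in_ellipse(pc$x, pc$y, e)
    vals <- vals + e$value * inside
  }
  image_grid(vals, pixel_size)
}

#' Default head phantom
#'
#' A deterministic stand-in for a transverse head section: a high-intensity
#' outer ring (skull) built from two concentric ellipses (the inner one
#' subtracts the ring value and adds the tissue background), a brain-tissue
#' interior, and two small off-center high-contrast "lesion" ellipses. All
#' structures fit inside a unit bounding radius.
#'
#' @return A [phantom_spec()] with bounding radius 1.
#' @export
#' @examples
#' ph <- default_head_phantom()
#' img <- rasterize(ph, 128, 2 / 128)
default_head_phantom <- function() {
  phantom_spec(list(
    # skull: bright outer ellipse, interior carved back down to 0
    ellipse(0, 0, 0.92, 0.86, 0, 2.0),
    ellipse(0, 0, 0.82, 0.76, 0, -2.0),
    # brain tissue background
    ellipse(0, 0, 0.80, 0.74, 0, 1.0),
    # ventricle-like low region
    ellipse(-0.12, 0.05, 0.22, 0.31, 18, -0.2),
    # lesions: small, off-center, high contrast
    ellipse(0.35, -0.25, 0.10, 0.07, -30, 0.8),
    ellipse(-0.30, -0.35, 0.05, 0.05, 0, 0.6)
  ), bounding_radius = 1)
}

#' Rotate a phantom by 90 degrees counterclockwise
#'
#' Rotates every ellipse about the isocenter. Useful for the
#' rotation-consistency property of the rasterizer.
#'
#' @param spec A [phantom_spec()].
#' @param quarters Number of 90-degree counterclockwise quarter turns.
#' @return The rotated [phantom_spec()].
#' @export
rotate_phantom_90 <- function(spec, quarters = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  q <- ((quarters %% 4) + 4) %% 4
  ells <- lapply(spec$ellipses, function(e) {
    cx <- e$cx; cy <- e$cy
    for (k in seq_len(q)) {
      tmp <- cx; cx <- -cy; cy <- tmp
    }
    ellipse(cx, cy, e$a, e$b, e$theta_deg + 90 * q, e$value)
  })
  phantom_spec(ells, spec$bounding_radius)
}

#' Rotate an image grid by 90 degrees counterclockwise
#'
#' Exact pixel permutation under the centered-grid convention: the pixel at
#' physical position (x, y) moves to (-y, x).
#'
#' @param grid An [image_grid()].
#' @param quarters Number of counterclockwise quarter turns.
#' @return The rotated [image_grid()].
#' @export
rotate_grid_90 <- function(grid, quarters = 1) {
  stopifnot(inherits(grid, "image_grid"))
  v <- grid$values
  q <- ((quarters %% 4) + 4) %% 4
  for (k in seq_len(q)) {
    # CCW: new (i', j') = (n + 1 - j, i) picks old (i, j)
    v <- t(v)[nrow(v):1, , drop = FALSE]
  }
  image_grid(v, grid$pixel_size)
}
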