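#' Fan-beam acquisition geometry
#'
#' Describes a full-turn fan-beam acquisition with a flat, equispaced virtual
#' detector through the isocenter. View angles are uniform,
#' `beta_k = k * 360 / n_views` degrees for `k = 1..n_views`, so the four
#' quarter-turn view regions are the half-open intervals (0, 90], (90, 180],
#' (180, 270], (270, 360].
#'
#' Geometric convention (the single convention used throughout): at view
#' angle `beta` the source sits at polar angle `beta + 90` degrees, distance
#' `D` from the isocenter; the detector coordinate `s` is measured along the
#' direction `(cos beta, sin beta)` on the virtual detector line through the
#' isocenter. Under this convention a point at polar coordinates `(r, phi)`
#' projects to `s' = D r cos(beta - phi) / (D + r sin(beta - phi))` and has
#' distance-ratio weight `U = (D + r sin(beta - phi)) / D`.
#'
#' @param D Source-to-isocenter distance; must exceed the object radius.
#' @param n_views Number of views over the full turn (>= 4).
#' @param n_bins Detector bin count.
#' @param bin_spacing Detector bin spacing on the virtual detector.
#' @return An object of class `"fan_geometry"`.
#' @export
fan_geometry <- function(D, n_views, n_bins, bin_spacing) {
  stopifnot(is.numeric(D), D > 0,
            is.numeric(n_views), n_views >= 4, n_views == round(n_views),
            is.numeric(n_bins), n_bins >= 2, n_bins == round(n_bins),
            is.numeric(bin_spacing), bin_spacing > 0)
  structure(list(D = as.numeric(D), n_views = as.integer(n_views),
                 n_bins = as.integer(n_bins),
                 bin_spacing = as.numeric(bin_spacing)),
            class = "fan_geometry")
}

#' View angles of a fan-beam geometry, degrees
#'
#' @param geom A [fan_geometry()].
#' @return Numeric vector `k * 360 / n_views`, `k = 1..n_views`.
#' @export
view_angles_deg <- function(geom) {
  stopifnot(inherits(geom, "fan_geometry"))
  seq_len(geom$n_views) * (360 / geom$n_views)
}

#' Detector bin center coordinates
#'
#' Bins are equispaced and centered at s = 0: bin j sits at
#' `(j - (n_bins + 1) / 2) * bin_spacing`. For odd `n_bins` the middle bin is
#' exactly the central ray.
#'
#' @param geom A [fan_geometry()].
#' @return Numeric vector of length `n_bins`.
#' @export
detector_coords <- function(geom) {
  stopifnot(inherits(geom, "fan_geometry"))
  (seq_len(geom$n_bins) - (geom$n_bins + 1) / 2) * geom$bin_spacing
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat("fan_geometry: D =", x$D, ",", x$n_views, "views,", x$n_bins,
      "bins, bin_spacing =", x$bin_spacing, "\n")
  invisible(x)
}

#' Construct a sinogram
#'
#' @param values `n_views`-by-`n_bins` matrix of line integrals; row k is the
#'   view at angle `beta_k`.
#' @param geometry A [fan_geometry()].
#' @return An object of class `"sinogram"`.
#' @export
sinogram <- function(values, geometry) {
  stopifnot(inherits(geometry, "fan_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != geometry$n_views || ncol(values) != geometry$n_bins)
    stop("sinogram shape (", nrow(values), "x", ncol(values),
         ") does not match geometry (", geometry$n_views, "x",
         geometry$n_bins, ")")
  if (!all(is.finite(values))) stop("sinogram values must be finite")
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat("sinogram: ", x$geometry$n_views, " views x ", x$geometry$n_bins,
      " bins, D = ", x$geometry$D, "\n", sep = "")
  invisible(x)
}

#' Source position for a view
#'
#' @param geom A [fan_geometry()].
#' @param beta_deg View angle, degrees.
#' @return Length-2 numeric `(x, y)`: the source at polar angle
#'   `beta_deg + 90`, distance `D`.
#' @export
source_position <- function(geom, beta_deg) {
  b <- beta_deg * pi / 180
  c(-geom$D * sin(b), geom$D * cos(b))
}

#' Ray through a detector coordinate
#'
#' Returns the ray from the source at view angle `beta_deg` through the
#' virtual-detector coordinate `s`. It is the geometric inverse of
#' [compute_sprime()]: any point `(r, phi)` with
#' `compute_sprime(r, phi, beta_deg, D) == s` lies on this ray.
#'
#' @param geom A [fan_geometry()].
#' @param beta_deg View angle, degrees.
#' @param s Detector coordinate on the virtual detector.
#' @return List with `point` (the source) and unit `direction`.
#' @export
ray_for <- function(geom, beta_deg, s) {
  stopifnot(inherits(geom, "fan_geometry"))
  src <- source_position(geom, beta_deg)
  b <- beta_deg * pi / 180
  det_pt <- c(s * cos(b), s * sin(b))
  d <- det_pt - src
  d <- d / sqrt(sum(d^2))
  list(point = src, direction = d)
}
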