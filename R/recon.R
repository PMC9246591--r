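#' Fan-beam distance-ratio weight U
#'
#' For a point at polar coordinates `(r, phi)` seen from the view at angle
#' `beta`, the dimensionless distance ratio is
#' `U = (D + r * sin(beta - phi)) / D`: the distance from the source to the
#' point, measured along the central-ray direction, over the source
#' distance. The back-projection accumulates filtered detector samples with
#' weight `1 / U^2`.
#'
#' @param r Radius (>= 0, < D). Vectorized.
#' @param phi_deg Point polar angle, degrees.
#' @param beta_deg View angle, degrees.
#' @param D Source-to-isocenter distance.
#' @return `U`, dimensionless; strictly positive for `r < D`.
#' @export
#' @examples
#' compute_U(0, 0, 45, 4)            # 1
#' compute_U(2, 0, 90, 4)            # 1.5
compute_U <- function(r, phi_deg, beta_deg, D) {
  check_radius(r, D)
  (D + r * sin((beta_deg - phi_deg) * pi / 180)) / D
}

#' Fan-beam virtual-detector coordinate s'
#'
#' The flat-detector coordinate (measured on the virtual detector through
#' the isocenter) at which the point `(r, phi)` is sampled for the view at
#' angle `beta`:
#' `s' = D * r * cos(beta - phi) / (D + r * sin(beta - phi))`.
#'
#' @inheritParams compute_U
#' @return Detector coordinate, same length unit as `r` and `D`.
#' @export
#' @examples
#' compute_sprime(0.7, 30, 30, 4)    # beta == phi: s' = r
compute_sprime <- function(r, phi_deg, beta_deg, D) {
  check_radius(r, D)
  d <- (beta_deg - phi_deg) * pi / 180
  D * r * cos(d) / (D + r * sin(d))
}

check_radius <- function(r, D) {
  if (any(r < 0)) stop("'r' must be >= 0")
  if (any(r >= D)) stop("'r' must be < D (the 1/U^2 weight requires U > 0)")
  invisible(TRUE)
}

#' Operation counter
#'
#' A mutable counter recording the number of sine/cosine evaluations
#' (`trig_evals`) and `(U, s')` geometry-pair computations (`geom_evals`)
#' performed by a back-projector, used to quantify the saving of the
#' symmetry-accelerated algorithm over the naive one.
#'
#' @return An object of class `"op_counter"` with both counts zero.
#' @export
new_op_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$trig_evals <- 0
  e$geom_evals <- 0
  class(e) <- "op_counter"
  e
}

counter_add <- function(counter, trig = 0, geom = 0) {
  if (!is.null(counter)) {
    counter$trig_evals <- counter$trig_evals + trig
    counter$geom_evals <- counter$geom_evals + geom
  }
  invisible(counter)
}

#' @export
print.op_counter <- function(x, ...) {
  cat("op_counter: trig_evals =", x$trig_evals,
      ", geom_evals =", x$geom_evals, "\n")
  invisible(x)
}

#' @export
as.list.op_counter <- function(x, ...) {
  list(trig_evals = x$trig_evals, geom_evals = x$geom_evals)
}

#' Cosine pre-weight for flat-detector fan-beam data
#'
#' Multiplies entry `(beta, s)` by `D / sqrt(D^2 + s^2)`, the standard
#' flat-detector pre-weight that converts fan-beam line integrals into the
#' form the ramp filter expects.
#'
#' @param sino A [sinogram()].
#' @return The pre-weighted [sinogram()].
#' @export
cos_preweight <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  D <- sino$geometry$D
  s <- detector_coords(sino$geometry)
  w <- D / sqrt(D^2 + s^2)
  sinogram(sweep(sino$values, 2, w, `*`), sino$geometry)
}

#' Ram-Lak ramp filter
#'
#' Convolves each view with the discrete ramp kernel
#' `h(0) = 1 / (4 ds^2)`, `h(m) = 0` for even `m != 0`,
#' `h(m) = -1 / (pi^2 m^2 ds^2)` for odd `m`, scaled by the bin spacing
#' `ds`, via FFT with zero padding to avoid circular wrap-around. Linear in
#' the input.
#'
#' @param sino A [sinogram()] (pre-weighted for fan-beam use).
#' @return The filtered [sinogram()].
#' @export
ramp_filter <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  nb <- sino$geometry$n_bins
  if (nb < 3) stop("ramp filter requires n_bins >= 3")
  ds <- sino$geometry$bin_spacing
  kern <- ramp_kernel(nb, ds)
  L <- 2^ceiling(log2(2 * nb))
  kpad <- numeric(L)
  kpad[1] <- kern[nb]                      # lag 0
  kpad[1 + seq_len(nb - 1)] <- kern[nb + seq_len(nb - 1)]   # positive lags
  kpad[L + 1 - seq_len(nb - 1)] <- kern[nb - seq_len(nb - 1)] # negative lags
  Hf <- stats::fft(kpad)
  P <- rbind(t(sino$values), matrix(0, L - nb, sino$geometry$n_views))
  Q <- Re(stats::mvfft(stats::mvfft(P) * Hf, inverse = TRUE)) / L
  sinogram(t(Q[seq_len(nb), , drop = FALSE]) * ds, sino$geometry)
}

# discrete ramp kernel over lags -(nb-1)..(nb-1); element nb is lag 0
ramp_kernel <- function(nb, ds) {
  m <- -(nb - 1):(nb - 1)
  h <- numeric(length(m))
  h[m == 0] <- 1 / (4 * ds^2)
  odd <- m %% 2 != 0
  h[odd] <- -1 / (pi^2 * m[odd]^2 * ds^2)
  h
}

# linear interpolation of detector row q at fractional bin positions u
# (1-based); zero outside the detector support.
interp_row <- function(q, u) {
  nb <- length(q)
  i0 <- floor(u)
  w <- u - i0
  out <- numeric(length(u))
  ok0 <- i0 >= 1 & i0 <= nb
  ok1 <- i0 >= 0 & i0 <= nb - 1
  out[ok0] <- out[ok0] + (1 - w[ok0]) * q[i0[ok0]]
  out[ok1] <- out[ok1] + w[ok1] * q[i0[ok1] + 1]
  out
}

check_backproject_inputs <- function(qsino, n, pixel_size) {
  stopifnot(inherits(qsino, "sinogram"))
  if (!is.numeric(n) || n < 1 || n != round(n)) stop("'n' must be a positive integer")
  if (!is.numeric(pixel_size) || pixel_size <= 0) stop("'pixel_size' must be > 0")
  if (qsino$geometry$n_views < 4) stop("need n_views >= 4")
  # corner pixel center must stay strictly inside the source circle
  rmax <- (n - 1) / 2 * pixel_size * sqrt(2)
  if (rmax >= qsino$geometry$D)
    stop("grid extends to radius ", signif(rmax, 6),
         " >= source distance D = ", qsino$geometry$D,
         "; sinogram geometry and grid conventions are incompatible")
  invisible(TRUE)
}

#' Naive fan-beam weighted back-projection
#'
#' Reference back-projector: for every pixel `(r, phi)` and every view
#' `beta` it evaluates the geometry pair `(U, s')` directly and accumulates
#' `q(beta, s') / U^2 * dbeta` (in radians), with linear interpolation
#' between the two detector bins bracketing `s'` and zero contribution where
#' `s'` falls off the detector. The counter is incremented by 2 trig
#' evaluations and 1 geometry pair per (pixel, view).
#'
#' @param qsino A pre-weighted, ramp-filtered [sinogram()] (see
#'   [cos_preweight()], [ramp_filter()]).
#' @param n Output grid side, pixels.
#' @param pixel_size Output pixel size.
#' @param counter Optional [new_op_counter()]; updated in place.
#' @return An [image_grid()].
#' @export
backproject_naive <- function(qsino, n, pixel_size, counter = NULL) {
  check_backproject_inputs(qsino, n, pixel_size)
  geom <- qsino$geometry
  D <- geom$D
  nb <- geom$n_bins
  ds <- geom$bin_spacing
  off <- (nb + 1) / 2
  pc <- pixel_centers(n, pixel_size)
  r <- sqrt(pc$x^2 + pc$y^2)
  phi <- atan2(pc$y, pc$x)
  dim(r) <- dim(phi) <- NULL
  npix <- n * n
  betas <- view_angles_deg(geom) * pi / 180
  dbeta <- 2 * pi / geom$n_views
  acc <- numeric(npix)
  for (k in seq_len(geom$n_views)) {
    d <- betas[k] - phi
    sd <- sin(d); cd <- cos(d)
    den <- D + r * sd
    U <- den / D
    sp <- D * r * cd / den
    acc <- acc + interp_row(qsino$values[k, ], sp / ds + off) / U^2
    counter_add(counter, trig = 2 * npix, geom = npix)
  }
  image_grid(matrix(acc * dbeta, n, n), pixel_size)
}

#' Partition a grid into 90-degree symmetry orbits
#'
#' Groups the pixels of an n-by-n centered grid into orbits of four pixels
#' related by successive 90-degree rotations about the isocenter: the orbit
#' of `E(r, phi)` is `E, E1(r, phi + 90), E2(r, phi + 180),
#' E3(r, phi + 270)`. All members share the radius `r` exactly; for odd `n`
#' the center pixel is a singleton orbit. Orbit count is `(n^2 - c) / 4 + c`
#' with `c = 1` for odd `n`, else 0.
#'
#' @param n Grid side, pixels (>= 1).
#' @param pixel_size Physical pixel size.
#' @return List with components `members` (orbit-count x 4 matrix of
#'   column-major pixel indices, columns in order phi, phi+90, phi+180,
#'   phi+270; the singleton center row, if present, repeats the center
#'   index), `r` (shared radius per orbit), `phi_deg` (polar angle of the
#'   first member, in (0, 360]), and `singleton` (logical per orbit).
#' @export
build_symmetry_orbits <- function(n, pixel_size) {
  if (!is.numeric(n) || n < 1 || n != round(n)) stop("'n' must be a positive integer")
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  idx <- function(i, j) (j - 1L) * n + i
  id0 <- idx(i, j)
  id1 <- idx(n + 1L - j, i)              # 90 deg CCW
  id2 <- idx(n + 1L - i, n + 1L - j)     # 180 deg
  id3 <- idx(j, n + 1L - i)              # 270 deg
  rep_id <- pmin(id0, id1, id2, id3)
  keep <- id0 == rep_id
  members <- cbind(id0, id1, id2, id3)[keep, , drop = FALSE]
  c0 <- (n + 1) / 2
  x <- (j[keep] - c0) * pixel_size
  y <- (c0 - i[keep]) * pixel_size
  r <- sqrt(x^2 + y^2)
  phi <- atan2(y, x) * 180 / pi
  phi <- ifelse(phi <= 0, phi + 360, phi)   # (0, 360]
  list(members = members, r = r, phi_deg = phi,
       singleton = members[, 1] == members[, 2])
}

#' Quadrant-symmetry accelerated fan-beam back-projection
#'
#' Mathematically identical accumulation to [backproject_naive()], organized
#' around the 90-degree symmetry of the centered grid and of the view
#' angles. The views are split into four quarter-turn regions
#' `(0, 90], (90, 180], (180, 270], (270, 360]` and the pixels into
#' four-member rotation orbits. For each orbit and each first-region view
#' `beta1` the algorithm evaluates `sin(beta1 - phi)` and `cos(beta1 - phi)`
#' once (2 trig evaluations) and forms the four distinct `(U, s')` pairs
#'
#' \describe{
#'   \item{P0}{`U = (D + r sin) / D`, `s' =  D r cos / (D + r sin)`}
#'   \item{P1}{`U = (D - r cos) / D`, `s' =  D r sin / (D - r cos)`}
#'   \item{P2}{`U = (D - r sin) / D`, `s' = -D r cos / (D - r sin)`}
#'   \item{P3}{`U = (D + r cos) / D`, `s' = -D r sin / (D + r cos)`}
#' }
#'
#' (4 geometry pairs, not 16) using the quarter-turn sign/swap identities of
#' the sine and cosine. Pair `P_p` serves orbit member `m` in view region
#' `q` whenever `p = (m - q + 1) mod 4`, which distributes the 16
#' (member, region) contributions per orbit and `beta1`. For even `n` the
#' counters therefore end at exactly 1/4 of the naive geometry evaluations
#' and 1/16 of the naive trig evaluations.
#'
#' @inheritParams backproject_naive
#' @return An [image_grid()]; equal to the naive result up to floating-point
#'   regrouping (about 1e-6 relative).
#' @export
backproject_symmetry <- function(qsino, n, pixel_size, counter = NULL) {
  check_backproject_inputs(qsino, n, pixel_size)
  geom <- qsino$geometry
  if (geom$n_views %% 4 != 0)
    stop("the symmetry back-projector requires n_views divisible by 4 ",
         "(got ", geom$n_views, ") so the four quarter-turn view regions ",
         "contain equal counts")
  D <- geom$D
  nb <- geom$n_bins
  ds <- geom$bin_spacing
  off <- (nb + 1) / 2
  V <- geom$n_views
  V4 <- V %/% 4
  dbeta <- 2 * pi / V
  orbits <- build_symmetry_orbits(n, pixel_size)
  four <- !orbits$singleton
  mem <- orbits$members[four, , drop = FALSE]
  r <- orbits$r[four]
  phi <- orbits$phi_deg[four] * pi / 180
  norb <- length(r)
  acc <- numeric(n * n)
  qv <- qsino$values
  betas1 <- seq_len(V4) * (360 / V) * pi / 180   # first-region views (0, 90]
  for (k in seq_len(V4)) {
    d <- betas1[k] - phi
    sd <- sin(d); cd <- cos(d)
    counter_add(counter, trig = 2 * norb, geom = 4 * norb)
    rs <- r * sd; rc <- r * cd
    den <- list(D + rs, D - rc, D - rs, D + rc)
    U2 <- lapply(den, function(z) (z / D)^2)
    su <- list((D * rc) / den[[1]], (D * rs) / den[[2]],
               (-D * rc) / den[[3]], (-D * rs) / den[[4]])
    for (q in 1:4) {
      row <- qv[(q - 1L) * V4 + k, ]
      for (m in 0:3) {
        p <- ((m - (q - 1)) %% 4) + 1
        contrib <- interp_row(row, su[[p]] / ds + off) / U2[[p]]
        tgt <- mem[, m + 1]
        acc[tgt] <- acc[tgt] + contrib
      }
    }
  }
  if (any(orbits$singleton)) {
    # center pixel (odd n): r = 0, U = 1, s' = 0 for every view; naive rule
    ctr <- orbits$members[orbits$singleton, 1]
    acc[ctr] <- acc[ctr] + sum(interp_row_scalar0(qv, off))
    counter_add(counter, trig = 2 * V, geom = V)
  }
  image_grid(matrix(acc * dbeta, n, n), pixel_size)
}

# interpolate every view row at fractional bin position `off` (s' = 0)
interp_row_scalar0 <- function(qv, off) {
  i0 <- floor(off); w <- off - i0
  nb <- ncol(qv)
  out <- numeric(nrow(qv))
  if (i0 >= 1 && i0 <= nb) out <- out + (1 - w) * qv[, i0]
  if (i0 + 1 >= 1 && i0 + 1 <= nb) out <- out + w * qv[, i0 + 1]
  out
}

#' Full filtered back-projection reconstruction
#'
#' Runs the standard flat-detector fan-beam chain — cosine pre-weight,
#' Ram-Lak ramp filter, `1/U^2`-weighted back-projection — with either the
#' naive or the symmetry-accelerated back-projector.
#'
#' @param sino A raw [sinogram()].
#' @param n Output grid side, pixels.
#' @param pixel_size Output pixel size.
#' @param method `"symmetry"` (default) or `"naive"`.
#' @return List with `image` (an [image_grid()]), `counter` (an
#'   [new_op_counter()] reflecting the back-projection stage), and `method`.
#' @export
#' @examples
#' g <- fan_geometry(D = 4, n_views = 72, n_bins = 65, bin_spacing = 2.2 / 64)
#' sino <- project_analytic(default_head_phantom(), g)
#' rec <- reconstruct(sino, n = 32, pixel_size = 2 / 32)
reconstruct <- function(sino, n, pixel_size, method = c("symmetry", "naive")) {
  method <- match.arg(method)
  q <- ramp_filter(cos_preweight(sino))
  # full-turn fan-beam data measures every ray twice; halve the filtered
  # views so the back-projection integral is normalized correctly
  q <- sinogram(q$values / 2, q$geometry)
  counter <- new_op_counter()
  img <- switch(method,
    naive = backproject_naive(q, n, pixel_size, counter),
    symmetry = backproject_symmetry(q, n, pixel_size, counter))
  list(image = img, counter = counter, method = method)
}
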