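#' Mean squared error between two images
#'
#' `MSE = 1/(m n) * sum_ij (I_ij - K_ij)^2` over all pixels.
#'
#' @param I,K Numeric matrices or [image_grid()] objects of identical shape.
#' @return Mean squared pixel difference.
#' @export
mse <- function(I, K) {
  I <- as_values(I); K <- as_values(K)
  check_same_shape(I, K)
  mean((I - K)^2)
}

#' Peak signal-to-noise ratio, decibels
#'
#' `PSNR = 10 * log10(max_val^2 / MSE)`. When the images are identical
#' (MSE = 0) the defined sentinel `Inf` is returned, not an error.
#'
#' @inheritParams mse
#' @param max_val Peak intensity `MAX` (> 0): 255 for 8-bit exports, the
#'   data range for floating-point grids.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
#' @examples
#' psnr(matrix(0, 2, 2), matrix(1, 2, 2), max_val = 1)   # 0 dB
psnr <- function(I, K, max_val) {
  if (!is.numeric(max_val) || max_val <= 0) stop("'max_val' must be > 0")
  m <- mse(I, K)
  if (m == 0) return(Inf)
  10 * log10(max_val^2 / m)
}

#' Structural similarity index
#'
#' Global (single-window) SSIM:
#' `SSIM = (2 mu_x mu_y + c1)(2 sigma_xy + c2) /
#'         ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`
#' with means, population variances (1/N) and covariance computed over the
#' whole image, and stabilizers `c1 = (k1 * max_val)^2`,
#' `c2 = (k2 * max_val)^2`. A mean-of-local-windows variant (uniform square
#' window) is available via `window`; the global form is the default.
#'
#' @inheritParams psnr
#' @param k1,k2 Stabilizer fractions (defaults 0.01 and 0.03).
#' @param window `NULL` (default) for the global statistic, or an odd
#'   integer window side for the sliding-window mean SSIM.
#' @return SSIM in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(I, K, max_val, k1 = 0.01, k2 = 0.03, window = NULL) {
  I <- as_values(I); K <- as_values(K)
  check_same_shape(I, K)
  if (!is.numeric(max_val) || max_val <= 0) stop("'max_val' must be > 0")
  c1 <- (k1 * max_val)^2
  c2 <- (k2 * max_val)^2
  if (is.null(window)) return(ssim_stat(I, K, c1, c2))
  if (window %% 2 != 1 || window < 3) stop("'window' must be an odd integer >= 3")
  h <- (window - 1) / 2
  vals <- c()
  for (ci in seq_len(nrow(I) - window + 1)) {
    for (cj in seq_len(ncol(I) - window + 1)) {
      ii <- ci:(ci + window - 1); jj <- cj:(cj + window - 1)
      vals <- c(vals, ssim_stat(I[ii, jj], K[ii, jj], c1, c2))
    }
  }
  mean(vals)
}

ssim_stat <- function(I, K, c1, c2) {
  N <- length(I)
  mx <- mean(I); my <- mean(K)
  vx <- mean((I - mx)^2)          # population (1/N) variance
  vy <- mean((K - my)^2)
  cxy <- mean((I - mx) * (K - my))
  (2 * mx * my + c1) * (2 * cxy + c2) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Image-quality report
#'
#' Convenience wrapper computing MSE, PSNR and SSIM of a test image against
#' a reference, recording the constants used.
#'
#' @inheritParams ssim
#' @return List of class `"quality_report"`: `mse`, `psnr`, `ssim`,
#'   `max_val`, `k1`, `k2`, `c1`, `c2`.
#' @export
quality_report <- function(I, K, max_val, k1 = 0.01, k2 = 0.03) {
  structure(list(mse = mse(I, K), psnr = psnr(I, K, max_val),
                 ssim = ssim(I, K, max_val, k1, k2),
                 max_val = max_val, k1 = k1, k2 = k2,
                 c1 = (k1 * max_val)^2, c2 = (k2 * max_val)^2),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("MSE  = %.6g\nPSNR = %.4f dB\nSSIM = %.6f\n(max_val = %g, c1 = %g, c2 = %g)\n",
              x$mse, x$psnr, x$ssim, x$max_val, x$c1, x$c2))
  invisible(x)
}

as_values <- function(x) {
  if (inherits(x, "image_grid")) x$values else as.matrix(x)
}

check_same_shape <- function(I, K) {
  if (!identical(dim(I), dim(K)))
    stop("image shapes differ: ", paste(dim(I), collapse = "x"), " vs ",
         paste(dim(K), collapse = "x"))
  invisible(TRUE)
}
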