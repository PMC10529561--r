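# Separable convolution utilities shared by the lowpass stage and SSIM.

# Normalized, truncated 1-D Gaussian kernel; radius defaults to ceil(3*sigma).
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive number", call. = FALSE)
  }
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 2-D convolution with a symmetric (odd-length) kernel applied
# along rows then columns. By default the input is extended symmetrically by
# the kernel radius; pass `pre_extended = TRUE` when the caller already holds
# an image padded by exactly `radius` on every side (the tiled path).
conv_sep <- function(img, kernel, pre_extended = FALSE) {
  r <- (length(kernel) - 1L) %/% 2L
  if (length(kernel) != 2L * r + 1L) stop("kernel must have odd length")
  if (r == 0L) return(as_gray_image(img) * kernel)
  ext <- if (pre_extended) as_gray_image(img)
         else extend_boundary(img, r, "symmetric")
  H <- nrow(ext) - 2L * r
  W <- ncol(ext) - 2L * r
  # vertical pass: rows collapse to H, columns keep their padding
  tmp <- matrix(0, H, ncol(ext))
  for (t in (-r):r) {
    tmp <- tmp + kernel[t + r + 1L] * ext[(r + 1L + t):(r + H + t), , drop = FALSE]
  }
  out <- matrix(0, H, W)
  for (t in (-r):r) {
    out <- out + kernel[t + r + 1L] * tmp[, (r + 1L + t):(r + W + t), drop = FALSE]
  }
  out
}

#' Gaussian lowpass filter
#'
#' Convolution with a normalized, truncated Gaussian kernel (truncation radius
#' `ceiling(3 * sigma)`, symmetric boundary extension). The kernel
#' coefficients sum to 1, so constants pass through unchanged. This produces
#' the lowpass base image from which the edge-carrying residual is formed.
#'
#' @param u A grayscale image matrix.
#' @param sigma Positive Gaussian standard deviation in pixels.
#' @return The smoothed image, same shape as `u`.
#' @export
lowpass_gaussian <- function(u, sigma) {
  conv_sep(as_gray_image(u), gaussian_kernel(sigma))
}
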