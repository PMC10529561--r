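#' Root mean square error
#'
#' @param ref,test Grayscale images of the same shape.
#' @return `sqrt(mean((ref - test)^2))`, in intensity units.
#' @export
rmse <- function(ref, test) {
  ref <- as_gray_image(ref)
  test <- as_gray_image(test)
  if (!identical(dim(ref), dim(test))) {
    stop("'ref' and 'test' must have the same shape", call. = FALSE)
  }
  sqrt(mean((ref - test)^2))
}

#' Peak signal-to-noise ratio
#'
#' `20 * log10(peak / rmse)`, in dB. Returns `Inf` when the images are
#' identical (rmse 0). `peak` defaults to 1, the dynamic range of the
#' internal intensity scale.
#'
#' @inheritParams rmse
#' @param peak Positive peak signal value.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(ref, test, peak = 1.0) {
  if (!is.numeric(peak) || length(peak) != 1L || !is.finite(peak) || peak <= 0) {
    stop("'peak' must be a single positive number", call. = FALSE)
  }
  e <- rmse(ref, test)
  if (e == 0) return(Inf)
  20 * log10(peak / e)
}

#' Structural similarity index
#'
#' Mean local SSIM with the standard literature settings: an 11x11 Gaussian
#' weighting window with sigma 1.5, stabilizing constants `C1 = (K1 * L)^2`
#' and `C2 = (K2 * L)^2` with `K1 = 0.01`, `K2 = 0.03` and dynamic range
#' `L = 1` on the internal scale. Local means, variances and covariance are
#' computed with the Gaussian window under symmetric boundary extension.
#'
#' @inheritParams rmse
#' @return The mean SSIM over the image, in `[-1, 1]`; 1 for identical
#'   images.
#' @export
ssim <- function(ref, test) {
  ref <- as_gray_image(ref)
  test <- as_gray_image(test)
  if (!identical(dim(ref), dim(test))) {
    stop("'ref' and 'test' must have the same shape", call. = FALSE)
  }
  if (min(dim(ref)) < 11L) {
    stop("ssim requires images of at least 11 x 11 pixels", call. = FALSE)
  }
  k <- gaussian_kernel(1.5, radius = 5L)  # 11-tap window
  C1 <- 0.01^2
  C2 <- 0.03^2
  mu1 <- conv_sep(ref, k)
  mu2 <- conv_sep(test, k)
  s11 <- conv_sep(ref * ref, k) - mu1 * mu1
  s22 <- conv_sep(test * test, k) - mu2 * mu2
  s12 <- conv_sep(ref * test, k) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Evaluation report for a denoised image
#'
#' @inheritParams rmse
#' @return A list of class `metric_report` with `psnr` (dB), `ssim` and
#'   `rmse`.
#' @export
metric_report <- function(ref, test) {
  structure(list(psnr = psnr(ref, test), ssim = ssim(ref, test),
                 rmse = rmse(ref, test)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("PSNR %.4f dB | SSIM %.4f | RMSE %.5f\n", x$psnr, x$ssim, x$rmse))
  invisible(x)
}

#' Intensity profile along a line segment
#'
#' Samples pixel values along the discrete segment from `p0` to `p1`
#' (Bresenham traversal), the line-graph diagnostic used to compare edge
#' rendition of a denoised image against its reference: profiles of the two
#' images along the same segment can be overlaid and their mean absolute
#' difference reported via [profile_overlap()].
#'
#' @param img A grayscale image.
#' @param p0,p1 Segment endpoints as `c(row, col)`, inside the image.
#' @return A data.frame of class `line_profile` with columns `position`
#'   (0-based distance step along the segment), `row`, `col`, `value`.
#' @export
line_profile <- function(img, p0, p1) {
  img <- as_gray_image(img)
  p0 <- as.integer(p0)
  p1 <- as.integer(p1)
  inb <- function(p) p[1] >= 1L && p[1] <= nrow(img) &&
                     p[2] >= 1L && p[2] <= ncol(img)
  if (length(p0) != 2L || length(p1) != 2L || !inb(p0) || !inb(p1)) {
    stop("segment endpoints must lie inside the image", call. = FALSE)
  }
  # Bresenham on (row, col)
  dr <- abs(p1[1] - p0[1]); dc <- abs(p1[2] - p0[2])
  sr <- sign(p1[1] - p0[1]); sc <- sign(p1[2] - p0[2])
  err <- dc - dr
  r <- p0[1]; cc <- p0[2]
  rows <- integer(0); cols <- integer(0)
  repeat {
    rows <- c(rows, r); cols <- c(cols, cc)
    if (r == p1[1] && cc == p1[2]) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; cc <- cc + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out <- data.frame(position = seq_along(rows) - 1L, row = rows, col = cols,
                    value = img[cbind(rows, cols)])
  class(out) <- c("line_profile", "data.frame")
  out
}

#' Overlap score between two intensity profiles
#'
#' Mean absolute difference of the sampled values of two profiles taken along
#' the same segment; 0 means the profiles overlap perfectly.
#'
#' @param a,b `line_profile` objects of equal length.
#' @return A non-negative scalar.
#' @export
profile_overlap <- function(a, b) {
  if (nrow(a) != nrow(b)) {
    stop("profiles must be sampled along the same segment", call. = FALSE)
  }
  mean(abs(a$value - b$value))
}
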