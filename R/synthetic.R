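#' Generate a piecewise-constant CT-like phantom
#'
#' Builds a synthetic ground-truth image qualitatively mimicking an abdominal
#' CT slice: a dark background, a large elliptical "body", `n_shapes`
#' randomly placed, randomly oriented ellipses filled with levels drawn from
#' `intensity_levels` (later shapes overwrite earlier ones, keeping the image
#' piecewise constant with sharp edges), and `lesion_count` small
#' low-contrast discs offset by `lesion_contrast` from their surroundings.
#' Deterministic: the same spec and seed give a bit-identical phantom, and
#' the caller's RNG state is left untouched.
#'
#' @param height,width Positive integer image dimensions.
#' @param n_shapes Number of random ellipses (0 gives a constant image at the
#'   background level).
#' @param intensity_levels Intensity palette in \[0, 1\]; the first entry is
#'   the background level, the second the body level.
#' @param lesion_count Number of small low-contrast lesion discs.
#' @param lesion_contrast Intensity offset of lesions over their local
#'   surroundings.
#' @param seed Integer seed.
#' @return A `height x width` grayscale image in \[0, 1\].
#' @export
generate_phantom <- function(height = 128L, width = 128L, n_shapes = 6L,
                             intensity_levels = c(0.05, 0.2, 0.35, 0.5, 0.65, 0.8),
                             lesion_count = 3L, lesion_contrast = 0.08,
                             seed = 1L) {
  height <- as.integer(height)
  width <- as.integer(width)
  n_shapes <- as.integer(n_shapes)
  lesion_count <- as.integer(lesion_count)
  if (height < 1L || width < 1L) stop("invalid phantom dimensions", call. = FALSE)
  if (length(intensity_levels) < 1L) {
    stop("'intensity_levels' must not be empty", call. = FALSE)
  }
  if (any(intensity_levels < 0) || any(intensity_levels > 1)) {
    stop("'intensity_levels' must lie in [0, 1]", call. = FALSE)
  }
  if (n_shapes < 0L || lesion_count < 0L) {
    stop("'n_shapes' and 'lesion_count' must be non-negative", call. = FALSE)
  }
  img <- matrix(intensity_levels[1], height, width)
  if (n_shapes == 0L && lesion_count == 0L) return(img)
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  in_ellipse <- function(r0, c0, a, b, theta) {
    dr <- rr - r0
    dc <- cc - c0
    x <- cos(theta) * dc + sin(theta) * dr
    y <- -sin(theta) * dc + cos(theta) * dr
    (x / a)^2 + (y / b)^2 <= 1
  }
  with_seed(seed, {
    if (n_shapes >= 1L) {
      # large body ellipse first, at the second palette level when available
      body_level <- intensity_levels[min(2L, length(intensity_levels))]
      img[in_ellipse(height / 2, width / 2, 0.44 * width, 0.46 * height, 0)] <-
        body_level
      levels_pool <- if (length(intensity_levels) > 1L) {
        intensity_levels[-1]
      } else {
        intensity_levels
      }
      for (k in seq_len(n_shapes - 1L)) {
        r0 <- runif(1, 0.25 * height, 0.75 * height)
        c0 <- runif(1, 0.25 * width, 0.75 * width)
        a <- runif(1, 0.06, 0.22) * width
        b <- runif(1, 0.06, 0.22) * height
        theta <- runif(1, 0, pi)
        lev <- levels_pool[sample.int(length(levels_pool), 1L)]
        img[in_ellipse(r0, c0, a, b, theta)] <- lev
      }
    }
    for (k in seq_len(lesion_count)) {
      r0 <- runif(1, 0.3 * height, 0.7 * height)
      c0 <- runif(1, 0.3 * width, 0.7 * width)
      rad <- runif(1, 2, 4)
      sel <- in_ellipse(r0, c0, rad, rad, 0)
      base_lev <- img[round(r0), round(c0)]
      img[sel] <- min(1, base_lev + lesion_contrast)
    }
  })
  img
}

#' Add seeded Gaussian noise on the 8-bit sigma scale
#'
#' Degrades a clean image with i.i.d. additive Gaussian noise of standard
#' deviation `sigma8 / 255`, emulating low-dose CT acquisition at different
#' dose levels (`sigma8` between 5 and 30 spans light to heavy noise). The
#' result is deliberately not clipped to \[0, 1\], so the noise statistics
#' stay exact; clipping happens only on export.
#'
#' @param img A grayscale image.
#' @param sigma8 Positive noise standard deviation on the 8-bit (0-255)
#'   scale.
#' @param seed Integer seed.
#' @return `img` plus the seeded noise field.
#' @export
add_gaussian_noise <- function(img, sigma8, seed = 1L) {
  img <- as_gray_image(img)
  if (!is.numeric(sigma8) || length(sigma8) != 1L || !is.finite(sigma8) ||
      sigma8 <= 0) {
    stop("'sigma8' must be a single positive number", call. = FALSE)
  }
  noise <- with_seed(seed, rnorm(length(img), mean = 0, sd = sigma8 / 255))
  img + matrix(noise, nrow(img), ncol(img))
}
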