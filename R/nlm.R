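#' Non-local means parameters
#'
#' Bundles the parameters of the non-local means (NLM) filter. The search
#' window around a pixel `s` is the set of translations `d` with
#' `max(|d_row|, |d_col|) <= K`, i.e. a `(2K+1) x (2K+1)` window; patch
#' similarity is measured over a flat (unweighted) square patch of side
#' `2P+1`. `h` controls the degree of filtering: larger `h` tolerates larger
#' patch distances and averages more aggressively.
#'
#' @param K Non-negative integer search half-width (default 3, a 7x7 window).
#' @param P Non-negative integer patch half-width (default 5, an 11x11 patch).
#' @param h Positive filtering strength on the \[0, 1\] intensity scale
#'   (default 0.15).
#' @param boundary Boundary extension mode, `"symmetric"` or `"periodic"`.
#' @return An object of class `nlm_params`.
#' @export
nlm_params <- function(K = 3L, P = 5L, h = 0.15,
                       boundary = c("symmetric", "periodic")) {
  K <- as.integer(K)
  P <- as.integer(P)
  boundary <- match.arg(boundary)
  if (is.na(K) || K < 0L) stop("'K' must be a non-negative integer", call. = FALSE)
  if (is.na(P) || P < 0L) stop("'P' must be a non-negative integer", call. = FALSE)
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("'h' must be a single positive number", call. = FALSE)
  }
  structure(list(K = K, P = P, h = as.numeric(h), boundary = boundary),
            class = "nlm_params")
}

#' @export
print.nlm_params <- function(x, ...) {
  cat(sprintf("NLM parameters: K = %d (%dx%d window), P = %d (%dx%d patch), h = %g, boundary = %s\n",
              x$K, 2 * x$K + 1, 2 * x$K + 1, x$P, 2 * x$P + 1, 2 * x$P + 1,
              x$h, x$boundary))
  invisible(x)
}

#' Rational similarity kernel
#'
#' The weight kernel `g_h(x) = 1 / (1 + x^2 / h^2)` mapping a patch distance
#' `x >= 0` to a similarity weight in `(0, 1]`. It equals 1 at `x = 0`,
#' 0.5 at `x = h`, and decreases strictly in `x`. The rational form is used
#' instead of the Gaussian `exp(-x^2/h^2)` because it is cheaper and flatter
#' in the tails.
#'
#' @param x Non-negative patch distance(s); vectorized.
#' @param h Positive filtering strength.
#' @return Weight(s) in `(0, 1]`.
#' @examples
#' weight_kernel(0, 0.15)    # 1
#' weight_kernel(0.3, 0.15)  # 0.2
#' @export
weight_kernel <- function(x, h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("'h' must be a single positive number", call. = FALSE)
  }
  if (any(x < 0)) stop("'x' must be non-negative", call. = FALSE)
  1 / (1 + (x / h)^2)
}

# 2D cumulative sum (integral image), robust to single-row/column input.
cumsum2d <- function(D) {
  nr <- nrow(D)
  nc <- ncol(D)
  if (nr > 1L) D <- apply(D, 2, cumsum)
  D <- matrix(D, nr, nc)
  if (nc > 1L) D <- t(apply(D, 1, cumsum))
  matrix(D, nr, nc)
}

#' Prefix sums of squared differences for one translation
#'
#' For a translation `d = (d_row, d_col)`, forms the per-pixel squared
#' difference `(v(p) - v(p + d))^2` over the maximal region where both `p`
#' and `p + d` fall inside `img_ext`, and accumulates it into a running 2-D
#' prefix sum (integral image) `S`, so that the sum of squared differences
#' over any axis-aligned box can later be read with 4 corner lookups.
#' `img_ext` is expected to be boundary-extended by at least `K + P` so the
#' region of interest is fully covered.
#'
#' @param img_ext A (boundary-extended) grayscale image matrix.
#' @param d Integer translation `c(d_row, d_col)`.
#' @return A matrix `S` over the overlap region with attributes `translation`
#'   and `offset` (row/col offset of `S[1,1]` inside `img_ext`, zero-based).
#' @export
compute_prefix_ssd <- function(img_ext, d) {
  img_ext <- as_gray_image(img_ext)
  d <- as.integer(d)
  if (length(d) != 2L || any(is.na(d))) {
    stop("'d' must be an integer vector c(d_row, d_col)", call. = FALSE)
  }
  h <- nrow(img_ext)
  w <- ncol(img_ext)
  if (abs(d[1]) >= h || abs(d[2]) >= w) {
    stop("translation exceeds the available image extent", call. = FALSE)
  }
  r1 <- max(1L, 1L - d[1]); r2 <- min(h, h - d[1])
  c1 <- max(1L, 1L - d[2]); c2 <- min(w, w - d[2])
  D <- (img_ext[r1:r2, c1:c2, drop = FALSE] -
        img_ext[(r1 + d[1]):(r2 + d[1]), (c1 + d[2]):(c2 + d[2]),
                drop = FALSE])^2
  S <- cumsum2d(D)
  attr(S, "translation") <- d
  attr(S, "offset") <- c(r1 - 1L, c1 - 1L)
  S
}

#' Patch-similarity weight from a prefix-sum array
#'
#' Recovers the flat-patch sum of squared differences around `center` from a
#' prefix array `S` by inclusion-exclusion on the box corners (4 reads in 2-D,
#' 2 in 1-D), under the exclusive-prefix convention `S(0) = 0`: the
#' `(2P+1)`-sample box sum is `S(c+P) - S(c-P-1)` per axis. The weight is
#' `weight_kernel(box_sum, h)`.
#'
#' @param S Prefix array from [compute_prefix_ssd()]; a matrix (2-D) or a
#'   plain numeric vector (1-D illustration of the running-sum identity).
#' @param center Center location in `S` coordinates: `c(row, col)` for a
#'   matrix, a single index for a vector. Must be at least `P + 1` from the
#'   upper/left edge in the inclusive sense (index `center - P - 1` may be 0,
#'   meaning the implicit leading zero).
#' @param P Patch half-width.
#' @param h Filtering strength.
#' @return A similarity weight in `(0, 1]`.
#' @export
weight_from_prefix <- function(S, center, P, h) {
  P <- as.integer(P)
  if (is.matrix(S) && (nrow(S) == 1L || ncol(S) == 1L)) S <- as.vector(S)
  if (!is.matrix(S)) {
    ctr <- as.integer(center[1])
    if (ctr - P - 1L < 0L || ctr + P > length(S)) {
      stop("patch box exceeds the prefix array", call. = FALSE)
    }
    lo <- if (ctr - P - 1L == 0L) 0 else S[ctr - P - 1L]
    box <- S[ctr + P] - lo
  } else {
    i <- as.integer(center[1])
    j <- as.integer(center[2])
    if (i - P - 1L < 0L || j - P - 1L < 0L ||
        i + P > nrow(S) || j + P > ncol(S)) {
      stop("patch box exceeds the prefix array", call. = FALSE)
    }
    at <- function(r, c) if (r == 0L || c == 0L) 0 else S[r, c]
    box <- at(i + P, j + P) - at(i - P - 1L, j + P) -
           at(i + P, j - P - 1L) + at(i - P - 1L, j - P - 1L)
  }
  weight_kernel(max(box, 0), h)
}

# Shared driver of the fast path: `ext` is the image extended by `margin`
# (>= K + P) on each side; returns the denoised central H x W block. For each
# of the (2K+1)^2 translations it builds the squared-difference field once,
# turns it into an integral image, reads every pixel's flat-patch SSD with 4
# corner lookups (cost independent of P), and accumulates the weighted
# translate and the normalizer.
nlm_core_fast <- function(ext, H, W, K, P, h, margin) {
  num <- matrix(0, H, W)
  den <- matrix(0, H, W)
  ops <- 0
  rows_D <- (margin - P + 1L):(margin + H + P)
  cols_D <- (margin - P + 1L):(margin + W + P)
  nrD <- H + 2L * P
  ncD <- W + 2L * P
  rHi <- (2L * P + 2L):(2L * P + 1L + H)
  rLo <- 1:H
  cHi <- (2L * P + 2L):(2L * P + 1L + W)
  cLo <- 1:W
  for (dr in -K:K) {
    for (dc in -K:K) {
      D <- (ext[rows_D, cols_D, drop = FALSE] -
            ext[rows_D + dr, cols_D + dc, drop = FALSE])^2
      Sp <- matrix(0, nrD + 1L, ncD + 1L)
      Sp[-1L, -1L] <- cumsum2d(D)
      B <- Sp[rHi, cHi, drop = FALSE] - Sp[rLo, cHi, drop = FALSE] -
           Sp[rHi, cLo, drop = FALSE] + Sp[rLo, cLo, drop = FALSE]
      B[B < 0] <- 0  # guard against cancellation-induced tiny negatives
      Wd <- 1 / (1 + (B / h)^2)
      vt <- ext[(margin + 1L + dr):(margin + H + dr),
                (margin + 1L + dc):(margin + W + dc), drop = FALSE]
      num <- num + Wd * vt
      den <- den + Wd
      ops <- ops + length(D) + 6L * H * W
    }
  }
  out <- num / den
  attr(out, "ops") <- ops
  out
}

#' Fast non-local means via per-translation prefix sums
#'
#' The constructive NLM filter: for every translation `d` in the search
#' window, the squared-difference image against the translate is accumulated
#' into an integral image, from which every pixel's flat-patch distance is
#' read in O(1) (4 corner operations), making the per-translation cost
#' independent of the patch size. Numerically equivalent to
#' [nlm_bruteforce()] (same boundary mode, flat patch kernel) to within
#' floating-point accumulation error.
#'
#' @param img A grayscale image matrix.
#' @param params An [nlm_params()] object.
#' @return The filtered image (same shape); attribute `"ops"` carries an
#'   operation-count proxy for scaling checks.
#' @export
nlm_fast <- function(img, params = nlm_params()) {
  img <- as_gray_image(img)
  stopifnot(inherits(params, "nlm_params"))
  K <- params$K; P <- params$P
  if (K == 0L) {
    out <- img
    attr(out, "ops") <- 0
    return(out)
  }
  m <- K + P
  ext <- extend_boundary(img, m, params$boundary)
  nlm_core_fast(ext, nrow(img), ncol(img), K, P, params$h, m)
}

#' Brute-force non-local means (reference implementation)
#'
#' The naive sliding-window evaluation of the NLM average: for each pixel and
#' each of the `(2K+1)^2` candidate translations, the flat-patch sum of
#' squared differences is accumulated by an explicit double loop over the
#' patch. O(n K^2 P^2); used as the independent oracle for [nlm_fast()].
#'
#' @inheritParams nlm_fast
#' @return The filtered image matrix.
#' @export
nlm_bruteforce <- function(img, params = nlm_params()) {
  img <- as_gray_image(img)
  stopifnot(inherits(params, "nlm_params"))
  K <- params$K; P <- params$P
  if (K == 0L) return(img)
  m <- K + P
  ext <- extend_boundary(img, m, params$boundary)
  nlm_brute_cpp(ext, nrow(img), ncol(img), K, P, params$h)
}

#' Tiled non-local means with halo equivalence
#'
#' Runs [nlm_fast()] on disjoint tiles, each padded with a halo of
#' neighboring pixels. Because a pixel's output depends only on values within
#' `K + P` of it, a halo of at least `K + P` makes the tiled result identical
#' to the untiled one; a smaller halo is rejected.
#'
#' @inheritParams nlm_fast
#' @param tile Positive integer tile side in pixels.
#' @param halo Halo width; must be `>= K + P`. Defaults to `K + P`.
#' @return The filtered image, identical to `nlm_fast(img, params)`.
#' @export
nlm_tiled <- function(img, params = nlm_params(), tile = 64L, halo = NULL) {
  img <- as_gray_image(img)
  stopifnot(inherits(params, "nlm_params"))
  K <- params$K; P <- params$P
  tile <- as.integer(tile)
  if (is.na(tile) || tile < 1L) stop("'tile' must be >= 1", call. = FALSE)
  if (is.null(halo)) halo <- K + P
  halo <- as.integer(halo)
  if (halo < K + P) {
    stop(sprintf("insufficient halo: need >= K + P = %d, got %d", K + P, halo),
         call. = FALSE)
  }
  if (K == 0L) return(img)
  H <- nrow(img); W <- ncol(img)
  ext <- extend_boundary(img, halo, params$boundary)
  out <- matrix(0, H, W)
  for (r0 in seq(1L, H, by = tile)) {
    r1 <- min(r0 + tile - 1L, H)
    for (c0 in seq(1L, W, by = tile)) {
      c1 <- min(c0 + tile - 1L, W)
      sub <- ext[r0:(r1 + 2L * halo), c0:(c1 + 2L * halo), drop = FALSE]
      out[r0:r1, c0:c1] <- nlm_core_fast(sub, r1 - r0 + 1L, c1 - c0 + 1L,
                                         K, P, params$h, halo)
    }
  }
  out
}
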