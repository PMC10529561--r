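#' Validate and coerce a grayscale image
#'
#' The package's universal currency is a plain numeric matrix of real
#' intensities, nominally on the \[0, 1\] scale (values may drift outside that
#' range inside the pipeline, e.g. for unclipped noisy images; clipping happens
#' only on export to integer formats). This helper checks the contract every
#' stage relies on: a finite numeric matrix with at least one row and column.
#'
#' @param x A numeric matrix (or something coercible to one).
#' @return A double-storage numeric matrix.
#' @examples
#' img <- as_gray_image(matrix(runif(12), 3, 4))
#' @export
as_gray_image <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a gray image must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("a gray image needs height >= 1 and width >= 1", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("a gray image must contain only finite values", call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Extend image boundaries by reflection or periodic wrap
#'
#' Pads an image by `margin` pixels on every side so that patch and
#' search-window reads near the border stay in range. `"symmetric"` reflects
#' across the edge with the edge pixel included (a 1-D row `1 2 4` with margin
#' 1 becomes `1 1 2 4 4`); `"periodic"` wraps around (`4 1 2 4 1`).
#'
#' @param img A grayscale image matrix.
#' @param margin Non-negative integer padding width.
#' @param mode `"symmetric"` (default) or `"periodic"`.
#' @return A `(h + 2 margin) x (w + 2 margin)` matrix whose central block is
#'   `img` exactly.
#' @examples
#' extend_boundary(matrix(c(1, 2, 4), 1, 3), 1, "symmetric")
#' @export
extend_boundary <- function(img, margin, mode = c("symmetric", "periodic")) {
  img <- as_gray_image(img)
  mode <- match.arg(mode)
  margin <- as.integer(margin)
  if (length(margin) != 1L || is.na(margin) || margin < 0L) {
    stop("'margin' must be a single non-negative integer", call. = FALSE)
  }
  if (margin == 0L) return(img)
  h <- nrow(img)
  w <- ncol(img)
  if (mode == "symmetric" && margin >= min(h, w)) {
    stop("symmetric extension requires margin < min(height, width)",
         call. = FALSE)
  }
  idx <- function(n) {
    if (mode == "symmetric") {
      c(margin:1, 1:n, n:(n - margin + 1L))
    } else {
      ((((1L - margin):(n + margin)) - 1L) %% n) + 1L
    }
  }
  img[idx(h), idx(w), drop = FALSE]
}

# Run code with a private, restorable RNG stream so generators are
# reproducible without clobbering the caller's .Random.seed.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
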