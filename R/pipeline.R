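#' Full pipeline configuration
#'
#' Collects the NLM and morphological parameters plus execution options. The
#' defaults are the reference operating point used throughout: `K = 3`,
#' `P = 5`, `h = 0.15` for the NLM stage and `t = 0.15`, `s_size = 3`,
#' `c = 1.2` for the residual stage.
#'
#' @param nlm An [nlm_params()] object.
#' @param morph A [morph_params()] object.
#' @param tile Optional positive integer tile side for tiled execution.
#' @param halo Optional halo width for tiled execution; when `NULL` the
#'   minimum sufficient halo is used.
#' @param seed Integer seed recorded for any stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(nlm = nlm_params(), morph = morph_params(),
                            tile = NULL, halo = NULL, seed = 1L) {
  stopifnot(inherits(nlm, "nlm_params"), inherits(morph, "morph_params"))
  if (!is.null(tile)) {
    tile <- as.integer(tile)
    if (is.na(tile) || tile < 1L) stop("'tile' must be >= 1", call. = FALSE)
  }
  if (!is.null(halo)) halo <- as.integer(halo)
  structure(list(nlm = nlm, morph = morph, tile = tile, halo = halo,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  print(x$nlm)
  print(x$morph)
  if (!is.null(x$tile)) {
    cat(sprintf("Tiled execution: tile = %d, halo = %s\n", x$tile,
                if (is.null(x$halo)) "auto" else x$halo))
  }
  cat(sprintf("Seed: %d\n", x$seed))
  invisible(x)
}

# truncation radius of the lowpass kernel, used for halo budgets
lowpass_radius <- function(morph) as.integer(ceiling(3 * morph$lowpass_sigma))

#' Denoise an image with the full pipeline
#'
#' Runs the complete method: constructive NLM filtering, Gaussian lowpass of
#' the NLM output, signed residual split, amplitude/area screening with
#' geodesic reconstruction of each residual half, and contrast-controlled
#' recomposition `I_out = Io + c * (M(I_res+) - M(I_res-))`. All intermediate
#' images are retained in the result for inspection.
#'
#' @param img A grayscale image matrix.
#' @param cfg A [pipeline_config()].
#' @return An object of class `denoise_result`: a list with `u` (NLM
#'   output), `Io` (lowpass base), `res` (signed residual), `pair`
#'   (residual halves), `m_pos`, `m_neg` (processed halves), `out` (final
#'   image) and `cfg`.
#' @export
denoise <- function(img, cfg = pipeline_config()) {
  img <- as_gray_image(img)
  stopifnot(inherits(cfg, "pipeline_config"))
  u <- nlm_fast(img, cfg$nlm)
  attr(u, "ops") <- NULL
  finish_denoise(img, u, cfg)
}

# shared tail of the pipeline once u (and optionally Io) are known
finish_denoise <- function(img, u, cfg, Io = NULL) {
  mp <- cfg$morph
  if (is.null(Io)) Io <- lowpass_gaussian(u, mp$lowpass_sigma)
  res <- residual(u, Io)
  pair <- split_residual(res)
  m_pos <- morph_select(pair$pos, mp$t, mp$s_size, mp$connectivity)
  m_neg <- morph_select(pair$neg, mp$t, mp$s_size, mp$connectivity)
  out <- compose_output(Io, m_pos, m_neg, mp$c)
  structure(list(u = u, Io = Io, res = res, pair = pair,
                 m_pos = m_pos, m_neg = m_neg, out = out, cfg = cfg),
            class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("Denoise result: %d x %d image\n", nrow(x$out), ncol(x$out)))
  cat(sprintf("  residual range [%.4f, %.4f]; restored pixels: %d (+), %d (-)\n",
              min(x$res), max(x$res), sum(x$m_pos > 0), sum(x$m_neg > 0)))
  cat(sprintf("  output range [%.4f, %.4f]\n", min(x$out), max(x$out)))
  invisible(x)
}

#' Tiled execution of the full pipeline
#'
#' Computes the NLM stage and the lowpass convolution tile by tile with a
#' halo of surrounding pixels, then performs the residual split, screening
#' and geodesic reconstruction globally (reconstruction can propagate across
#' the whole image, so it is never tiled). Both tiled stages are local
#' operators, so with a sufficient halo (`K + P` for NLM plus the lowpass
#' truncation radius) the result is identical to [denoise()].
#'
#' @inheritParams denoise
#' @return A `denoise_result`, equal to the untiled one.
#' @export
denoise_tiled <- function(img, cfg = pipeline_config(tile = 64L)) {
  img <- as_gray_image(img)
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$tile)) stop("cfg$tile must be set for tiled execution",
                              call. = FALSE)
  K <- cfg$nlm$K; P <- cfg$nlm$P
  R <- lowpass_radius(cfg$morph)
  need <- K + P + R
  halo <- if (is.null(cfg$halo)) need else cfg$halo
  if (halo < need) {
    stop(sprintf("insufficient halo: need >= K + P + lowpass radius = %d, got %d",
                 need, halo), call. = FALSE)
  }
  u <- nlm_tiled(img, cfg$nlm, tile = cfg$tile, halo = K + P)
  # tiled lowpass: pad the assembled u once, convolve each tile from the pad
  k <- gaussian_kernel(cfg$morph$lowpass_sigma)
  ext_u <- extend_boundary(u, R, "symmetric")
  H <- nrow(img); W <- ncol(img)
  Io <- matrix(0, H, W)
  for (r0 in seq(1L, H, by = cfg$tile)) {
    r1 <- min(r0 + cfg$tile - 1L, H)
    for (c0 in seq(1L, W, by = cfg$tile)) {
      c1 <- min(c0 + cfg$tile - 1L, W)
      sub <- ext_u[r0:(r1 + 2L * R), c0:(c1 + 2L * R), drop = FALSE]
      Io[r0:r1, c0:c1] <- conv_sep(sub, k, pre_extended = TRUE)
    }
  }
  finish_denoise(img, u, cfg, Io = Io)
}

#' Read a grayscale image from PNG or TIFF
#'
#' 8-bit values map to `value / 255`, 16-bit to `value / 65535` (the png and
#' tiff readers perform this normalization). Multi-channel inputs trigger a
#' warning and only the first channel is used.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A grayscale image matrix in \[0, 1\].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  )
  if (is.list(x)) x <- x[[1]]
  if (length(dim(x)) == 3L) {
    warning("multi-channel image: using the first channel", call. = FALSE)
    x <- x[, , 1]
  }
  as_gray_image(x)
}

#' Write a grayscale image to PNG or TIFF
#'
#' Values are clipped to \[0, 1\] and quantized with round-half-even to the
#' requested bit depth. PNG output is always 8-bit; TIFF supports 8 or 16.
#'
#' @param img A grayscale image.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path, bit_depth = 16L) {
  img <- as_gray_image(img)
  bit_depth <- as.integer(bit_depth)
  if (!(bit_depth %in% c(8L, 16L))) stop("'bit_depth' must be 8 or 16",
                                         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  peak <- 2^bit_depth - 1
  q <- round(pmin(pmax(img, 0), 1) * peak) / peak
  if (ext == "png") {
    if (bit_depth != 8L) stop("PNG output is 8-bit; use TIFF for 16-bit",
                              call. = FALSE)
    png::writePNG(q, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(q, path, bits.per.sample = bit_depth)
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  }
  invisible(path)
}

# flat key = value serialization of a pipeline_config -------------------------

config_fields <- function(cfg) {
  list(K = cfg$nlm$K, P = cfg$nlm$P, h = cfg$nlm$h,
       boundary = cfg$nlm$boundary,
       t = cfg$morph$t, s_size = cfg$morph$s_size, c = cfg$morph$c,
       lowpass_sigma = cfg$morph$lowpass_sigma,
       connectivity = cfg$morph$connectivity,
       tile = cfg$tile, halo = cfg$halo, seed = cfg$seed)
}

fields_to_config <- function(f) {
  pipeline_config(
    nlm = nlm_params(K = f$K, P = f$P, h = f$h, boundary = f$boundary),
    morph = morph_params(t = f$t, s_size = f$s_size, c = f$c,
                         lowpass_sigma = f$lowpass_sigma,
                         connectivity = f$connectivity),
    tile = f$tile, halo = f$halo, seed = f$seed)
}

#' Write a pipeline configuration as flat key = value text
#'
#' @param cfg A [pipeline_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  f <- config_fields(cfg)
  fmt <- function(v) {
    if (is.null(v)) return(NULL)
    if (is.character(v)) v else format(v, digits = 17)
  }
  lines <- unlist(lapply(names(f), function(nm) {
    v <- fmt(f[[nm]])
    if (is.null(v)) NULL else paste(nm, "=", v)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pipeline configuration from flat key = value text
#'
#' Unknown keys are rejected; missing keys fall back to the package defaults.
#'
#' @param path File written by [write_config()] (or hand-edited in the same
#'   format; `#` starts a comment line).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 0L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  known <- c("K", "P", "h", "boundary", "t", "s_size", "c", "lowpass_sigma",
             "connectivity", "tile", "halo", "seed")
  if (any(!keys %in% known)) {
    stop("unknown config key: ", keys[!keys %in% known][1], call. = FALSE)
  }
  f <- config_fields(pipeline_config())
  for (i in seq_along(keys)) {
    f[[keys[i]]] <- if (keys[i] == "boundary") vals[i] else as.numeric(vals[i])
  }
  fields_to_config(f)
}
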