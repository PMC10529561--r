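# Independent oracles used to cross-check the package's implementations.
# These deliberately use the most naive formulation of each operation.

rand_img <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(h * w), h, w)
}

# Naive NLM: explicit quadruple loop, flat patch, rational kernel.
naive_nlm_r <- function(img, K, P, h, boundary = "symmetric") {
  m <- K + P
  ext <- extend_boundary(img, m, boundary)
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    ci <- i + m; cj <- j + m
    num <- 0; den <- 0
    for (dr in -K:K) for (dc in -K:K) {
      ssd <- 0
      for (pr in -P:P) for (pc in -P:P) {
        ssd <- ssd + (ext[ci + pr, cj + pc] - ext[ci + dr + pr, cj + dc + pc])^2
      }
      w <- 1 / (1 + (ssd / h)^2)
      num <- num + w * ext[ci + dr, cj + dc]
      den <- den + w
    }
    out[i, j] <- num / den
  }
  out
}

conn_offsets <- function(connectivity) {
  if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
}

# Flat grayscale dilation by the connectivity-defined neighborhood (plus
# center), via shifted copies padded with -Inf.
dilate_shift <- function(x, connectivity = 8) {
  H <- nrow(x); W <- ncol(x)
  acc <- x
  for (o in conn_offsets(connectivity)) {
    sh <- matrix(-Inf, H, W)
    rs <- max(1, 1 - o[1]):min(H, H - o[1])
    cs <- max(1, 1 - o[2]):min(W, W - o[2])
    sh[rs, cs] <- x[rs + o[1], cs + o[2]]
    acc <- pmax(acc, sh)
  }
  acc
}

# Geodesic reconstruction oracle: iterate marker <- min(dilate(marker), mask)
# until it stops changing.
reconstruct_iter <- function(mask, marker, connectivity = 8) {
  repeat {
    nxt <- pmin(dilate_shift(marker, connectivity), mask)
    if (identical(nxt, marker)) return(nxt)
    marker <- nxt
  }
}

# Stack-based flood-fill labeling oracle.
label_flood_r <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- conn_offsets(connectivity)
  nxt <- 0L
  for (j in 1:W) for (i in 1:H) {
    if (mask[i, j] == 0 || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        qi <- p[1] + o[1]; qj <- p[2] + o[2]
        if (qi < 1 || qi > H || qj < 1 || qj > W) next
        if (mask[qi, qj] != 0 && lab[qi, qj] == 0L) {
          lab[qi, qj] <- nxt
          stack[[length(stack) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

component_areas <- function(mask, connectivity = 8) {
  lab <- label_flood_r(mask, connectivity)
  if (!any(lab > 0L)) integer(0) else tabulate(lab[lab > 0L])
}

# Direct per-pixel Gaussian-window convolution oracle (symmetric boundary).
direct_gauss_filter <- function(img, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  wgt <- outer(k, k)
  ext <- extend_boundary(img, r, "symmetric")
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    out[i, j] <- sum(wgt * ext[i:(i + 2 * r), j:(j + 2 * r)])
  }
  out
}

# Per-pixel SSIM oracle with the same constants as the implementation.
oracle_ssim <- function(a, b) {
  r <- 5L
  k <- exp(-(-r:r)^2 / (2 * 1.5^2)); k <- k / sum(k)
  wgt <- outer(k, k)
  ea <- extend_boundary(a, r, "symmetric")
  eb <- extend_boundary(b, r, "symmetric")
  C1 <- 0.01^2; C2 <- 0.03^2
  H <- nrow(a); W <- ncol(a)
  acc <- 0
  for (i in 1:H) for (j in 1:W) {
    pa <- ea[i:(i + 2 * r), j:(j + 2 * r)]
    pb <- eb[i:(i + 2 * r), j:(j + 2 * r)]
    mu1 <- sum(wgt * pa); mu2 <- sum(wgt * pb)
    v1 <- sum(wgt * pa^2) - mu1^2
    v2 <- sum(wgt * pb^2) - mu2^2
    cv <- sum(wgt * pa * pb) - mu1 * mu2
    acc <- acc + ((2 * mu1 * mu2 + C1) * (2 * cv + C2)) /
                 ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2))
  }
  acc / (H * W)
}
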