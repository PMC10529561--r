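test_that("similarity kernel matches its closed form", {
  expect_equal(weight_kernel(0, 0.15), 1)
  for (h in c(0.05, 0.15, 1)) expect_equal(weight_kernel(h, h), 0.5)
  expect_equal(weight_kernel(0.3, 0.15), 0.2)
  expect_error(weight_kernel(0.1, 0), "positive")
  expect_error(weight_kernel(-0.1, 0.15), "non-negative")
  x <- seq(0, 2, by = 0.05)
  expect_true(all(diff(weight_kernel(x, 0.15)) < 0))
  expect_true(all(weight_kernel(x, 0.15) > 0 & weight_kernel(x, 0.15) <= 1))
})

test_that("prefix sums of squared differences accumulate correctly", {
  img <- rand_img(12, 12, seed = 2)
  S0 <- compute_prefix_ssd(img, c(0, 0))
  expect_true(all(S0 == 0))
  # the 1-D running-sum example: diffs [1,4,0] -> S = [1,5,5]
  S1 <- compute_prefix_ssd(matrix(c(1, 2, 4, 4), 1, 4), c(0, 1))
  expect_equal(as.vector(S1), c(1, 5, 5))
  # box sums recovered by inclusion-exclusion match direct loop sums
  img <- rand_img(16, 16, seed = 3)
  for (d in list(c(1, 0), c(0, 2), c(-2, 3), c(3, -1))) {
    S <- compute_prefix_ssd(img, d)
    off <- attr(S, "offset")
    sq <- (img[(1 + off[1]):(nrow(S) + off[1]), (1 + off[2]):(ncol(S) + off[2])] -
           img[(1 + off[1] + d[1]):(nrow(S) + off[1] + d[1]),
               (1 + off[2] + d[2]):(ncol(S) + off[2] + d[2])])^2
    for (box in list(c(1, 4, 1, 4), c(3, 9, 2, 11), c(5, 5, 7, 7))) {
      direct <- sum(sq[box[1]:box[2], box[3]:box[4]])
      at <- function(r, c) if (r == 0 || c == 0) 0 else S[r, c]
      viaS <- at(box[2], box[4]) - at(box[1] - 1, box[4]) -
              at(box[2], box[3] - 1) + at(box[1] - 1, box[3] - 1)
      expect_lt(abs(direct - viaS), 1e-10)
    }
    # prefix arrays are non-decreasing along each accumulation axis
    expect_true(all(apply(S, 2, diff) >= -1e-15))
    expect_true(all(apply(S, 1, diff) >= -1e-15))
  }
})

test_that("weights read from the prefix array equal brute-force patch sums", {
  # zero translation: weight exactly 1 at every feasible center
  img <- rand_img(10, 10, seed = 4)
  S <- compute_prefix_ssd(img, c(0, 0))
  for (ctr in list(c(3, 3), c(5, 8))) {
    expect_equal(weight_from_prefix(S, ctr, 2, 0.15), 1)
  }
  # 1-D example with the exclusive-prefix convention: box sum 5
  S1 <- compute_prefix_ssd(matrix(c(1, 2, 4, 4), 1, 4), c(0, 1))
  expect_equal(weight_from_prefix(S1, 2, 1, 0.15), weight_kernel(5, 0.15))
  # random 2-D: prefix read vs explicit double loop over the patch
  d <- c(2, -1); P <- 2; h <- 0.2
  S <- compute_prefix_ssd(img, d)
  off <- attr(S, "offset")
  for (ctr in list(c(4, 4), c(6, 5))) {
    i <- ctr[1]; j <- ctr[2]
    ssd <- 0
    for (pr in -P:P) for (pc in -P:P) {
      a <- c(i + off[1] + pr, j + off[2] + pc)
      ssd <- ssd + (img[a[1], a[2]] - img[a[1] + d[1], a[2] + d[2]])^2
    }
    expect_lt(abs(weight_from_prefix(S, ctr, P, h) - weight_kernel(ssd, h)),
              1e-10)
  }
  expect_error(weight_from_prefix(S, c(1, 1), 2, h), "exceeds")
})

test_that("brute-force NLM matches a naive pure-R evaluation", {
  img <- rand_img(8, 10, seed = 5)
  for (bd in c("symmetric", "periodic")) {
    for (kp in list(c(1, 1), c(2, 2))) {
      p <- nlm_params(K = kp[1], P = kp[2], h = 0.15, boundary = bd)
      expect_lt(max(abs(nlm_bruteforce(img, p) -
                        naive_nlm_r(img, kp[1], kp[2], 0.15, bd))), 1e-12)
    }
  }
})

test_that("NLM identity and convexity properties hold", {
  const <- matrix(0.42, 9, 11)
  p <- nlm_params(K = 2, P = 1, h = 0.1)
  expect_equal(nlm_bruteforce(const, p), const)
  expect_equal(nlm_fast(const, p), const, ignore_attr = TRUE)
  img <- rand_img(12, 9, seed = 6)
  p0 <- nlm_params(K = 0, P = 3, h = 0.1)
  expect_identical(nlm_bruteforce(img, p0), img)
  expect_equal(nlm_fast(img, p0), img, ignore_attr = TRUE)
  # convex combination: output within the window's min/max, range preserved
  K <- 2; P <- 2
  u <- nlm_fast(img, nlm_params(K, P, 0.15))
  ext <- extend_boundary(img, K + P, "symmetric")
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    win <- ext[(i + P):(i + P + 2 * K), (j + P):(j + P + 2 * K)]
    expect_gte(u[i, j], min(win) - 1e-12)
    expect_lte(u[i, j], max(win) + 1e-12)
  }
  expect_true(all(u >= 0 & u <= 1))
})

test_that("fast path reproduces brute force on random images", {
  cases <- list(list(64, 64, 3, 5), list(33, 47, 2, 3))
  for (cs in cases) {
    img <- rand_img(cs[[1]], cs[[2]], seed = cs[[1]])
    for (bd in c("symmetric", "periodic")) {
      p <- nlm_params(K = cs[[3]], P = cs[[4]], h = 0.15, boundary = bd)
      expect_lt(max(abs(nlm_fast(img, p) - nlm_bruteforce(img, p))), 1e-8)
    }
  }
})

test_that("filtering commutes with transposition", {
  img <- rand_img(20, 31, seed = 8)
  p <- nlm_params(K = 2, P = 3, h = 0.2)
  expect_lt(max(abs(t(nlm_fast(t(img), p)) - nlm_fast(img, p))), 1e-12)
})

test_that("large h drives the filter to the windowed box mean", {
  img <- rand_img(24, 18, seed = 9)
  K <- 3; P <- 2
  u <- nlm_fast(img, nlm_params(K, P, 1e6))
  ext <- extend_boundary(img, K + P, "symmetric")
  bm <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    bm[i, j] <- mean(ext[(i + P):(i + P + 2 * K), (j + P):(j + P + 2 * K)])
  }
  expect_lt(max(abs(u - bm)), 1e-6)
})

test_that("fast-path work scales linearly with image area", {
  p <- nlm_params(K = 3, P = 5, h = 0.15)
  ops1 <- attr(nlm_fast(rand_img(32, 32, seed = 10), p), "ops")
  ops2 <- attr(nlm_fast(rand_img(32, 64, seed = 11), p), "ops")
  expect_lt(ops2 / ops1, 2.2)
})

test_that("tiled NLM equals the untiled filter and rejects short halos", {
  img <- rand_img(50, 41, seed = 12)
  p <- nlm_params(K = 2, P = 3, h = 0.15)
  expect_lt(max(abs(nlm_tiled(img, p, tile = 16) - nlm_fast(img, p))), 1e-12)
  expect_lt(max(abs(nlm_tiled(img, p, tile = 100) - nlm_fast(img, p))), 1e-12)
  expect_error(nlm_tiled(img, p, tile = 16, halo = 4), "insufficient halo")
})
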