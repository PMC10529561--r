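test_that("Gaussian lowpass is normalized and matches direct convolution", {
  const <- matrix(0.3, 12, 12)
  expect_equal(lowpass_gaussian(const, 1.5), const)
  # unit impulse reproduces the kernel, summing to 1
  imp <- matrix(0, 25, 25); imp[13, 13] <- 1
  blurred <- lowpass_gaussian(imp, 1.5)
  expect_lt(abs(sum(blurred) - 1), 1e-12)
  expect_equal(blurred[13, 13], max(blurred))
  # direct per-pixel oracle on a small random image
  img <- rand_img(14, 11, seed = 20)
  expect_lt(max(abs(lowpass_gaussian(img, 1.2) - direct_gauss_filter(img, 1.2))),
            1e-12)
  expect_error(lowpass_gaussian(img, 0), "positive")
})

test_that("residual and its split obey the defining algebra", {
  u <- rand_img(10, 10, seed = 21)
  Io <- lowpass_gaussian(u, 1.5)
  res <- residual(u, Io)
  expect_equal(res + Io, u)
  expect_error(residual(u, matrix(0, 2, 2)), "shape")
  expect_equal(residual(matrix(0.5), matrix(0.3)), matrix(0.2))
  pr <- split_residual(matrix(c(-2, 0, 3), 1, 3))
  expect_equal(as.vector(pr$pos), c(0, 0, 3))
  expect_equal(as.vector(pr$neg), c(2, 0, 0))
  # random signed input: non-negativity, disjoint support, exact recomposition
  res <- matrix(rnorm(400, sd = 0.2), 20, 20)
  pr <- split_residual(res)
  expect_true(all(pr$pos >= 0) && all(pr$neg >= 0))
  expect_true(all(pr$pos * pr$neg == 0))
  expect_identical(pr$pos - pr$neg, res)
})

test_that("threshold mask selects by amplitude", {
  I <- matrix(c(0.1, 0.2, 0.05), 1, 3)
  expect_identical(as.vector(threshold_mask(I, 0.15)), c(0L, 1L, 0L))
  expect_true(all(threshold_mask(I, 0) == 1L))
  expect_true(all(threshold_mask(I, 0.3) == 0L))
})

test_that("area opening removes only undersized components", {
  m <- matrix(0L, 8, 8)
  m[2, 2:3] <- 1L                 # area 2
  m[5:6, 5:6] <- 1L; m[7, 5] <- 1L  # area 5 (8-connected)
  out <- area_open(m, 3, 8)
  expect_true(all(out[2, 2:3] == 0L))
  expect_equal(sum(out), 5)
  expect_identical(area_open(m, 1, 8), m)
  ones <- matrix(1L, 6, 7)
  expect_identical(area_open(ones, 42, 8), ones)
  # connectivity matters: a diagonal pair is one 8-component, two 4-components
  d <- matrix(0L, 5, 5); d[2, 2] <- 1L; d[3, 3] <- 1L
  expect_equal(sum(area_open(d, 2, 8)), 2)
  expect_equal(sum(area_open(d, 2, 4)), 0)
  # property: no surviving component below s_size, output is a subset
  set.seed(22)
  for (rep in 1:5) {
    mask <- matrix(as.integer(runif(400) > 0.6), 20, 20)
    for (conn in c(4L, 8L)) {
      out <- area_open(mask, 4, conn)
      expect_true(all(out <= mask))
      areas <- component_areas(out, conn)
      if (length(areas)) expect_true(all(areas >= 4))
      # components that were already large pass unchanged
      lab <- label_flood_r(mask, conn)
      big <- which(tabulate(lab[lab > 0L]) >= 4)
      for (b in big) expect_true(all(out[lab == b] == 1L))
    }
  }
})

test_that("labeling agrees with a flood-fill oracle", {
  set.seed(23)
  mask <- matrix(as.integer(runif(300) > 0.55), 15, 20)
  for (conn in c(4L, 8L)) {
    lab <- label_components(mask, conn)
    ref <- label_flood_r(mask, conn)
    expect_equal(max(lab), max(ref))
    # same partition (label numbering may differ): one-to-one cross table
    tab <- table(lab[mask == 1L], ref[mask == 1L])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("mask_to_levels maps 0/1 to the image extremes", {
  I <- matrix(c(0, 0.1, 0.3, 0.2), 2, 2)
  m <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  out <- mask_to_levels(m, I)
  expect_equal(out, matrix(c(0, 0.3, 0.3, 0), 2, 2))
  expect_true(all(mask_to_levels(matrix(1L, 2, 2), I) == 0.3))
  constI <- matrix(0.5, 2, 2)
  expect_true(all(mask_to_levels(m, constI) == 0.5))
})

test_that("geodesic reconstruction reaches the iterative fixed point", {
  img <- rand_img(9, 9, seed = 24)
  expect_equal(grayscale_reconstruct(img, img), img)
  floor_m <- matrix(min(img), 9, 9)
  expect_equal(grayscale_reconstruct(img, floor_m), floor_m)
  # two plateaus, marker seeding only the taller one
  mask <- matrix(0, 5, 5)
  mask[1:2, 1:2] <- 0.3
  mask[4:5, 4:5] <- 0.8
  marker <- matrix(0, 5, 5); marker[5, 5] <- 0.8
  rec <- grayscale_reconstruct(mask, marker)
  expect_true(all(rec[4:5, 4:5] == 0.8))
  expect_true(all(rec[1:2, 1:2] == 0))
  expect_equal(rec, reconstruct_iter(mask, marker))
  # random mask/marker pairs agree with the iterated-dilation oracle
  set.seed(25)
  for (rep in 1:6) {
    mk <- matrix(runif(15 * 13), 15, 13)
    mr <- pmin(mk, matrix(runif(15 * 13), 15, 13) * (runif(15 * 13) > 0.7))
    for (conn in c(4L, 8L)) {
      rec <- grayscale_reconstruct(mk, mr, conn)
      expect_lt(max(abs(rec - reconstruct_iter(mk, mr, conn))), 1e-12)
      expect_true(all(rec >= mr - 1e-15) && all(rec <= mk + 1e-15))
      # idempotence
      expect_equal(grayscale_reconstruct(mk, rec, conn), rec)
    }
  }
  expect_error(grayscale_reconstruct(mask, mask + 0.1), "marker")
})

test_that("residual-region selection is anti-extensive and respects t, s", {
  # blob of amplitude 0.4 (4 px) survives; 1-px spike of 0.9 is rejected
  I <- matrix(0, 9, 9)
  I[3:4, 3:4] <- 0.4
  I[7, 7] <- 0.9
  out <- morph_select(I, t = 0.15, s_size = 3)
  expect_equal(out[3:4, 3:4], matrix(0.4, 2, 2))
  expect_equal(out[7, 7], 0)
  expect_equal(morph_select(I, t = 0, s_size = 1), I)
  expect_true(all(morph_select(I, t = 1, s_size = 1) == 0))
  # anti-extensivity and monotonicity on random non-negative inputs
  set.seed(26)
  for (rep in 1:4) {
    I <- abs(matrix(rnorm(18 * 16, sd = 0.1), 18, 16))
    I[5:8, 5:9] <- I[5:8, 5:9] + 0.3
    M1 <- morph_select(I, 0.1, 2)
    expect_true(all(M1 >= 0) && all(M1 <= I + 1e-15))
    M2 <- morph_select(I, 0.2, 2)
    expect_true(all(M2 <= M1 + 1e-15))        # larger t selects less
    M3 <- morph_select(I, 0.1, 8)
    expect_true(all(M3 <= M1 + 1e-15))        # larger s_size selects less
  }
})

test_that("single-pixel impulses never survive the size screen", {
  set.seed(27)
  I <- matrix(0, 20, 20)
  idx <- cbind(c(3, 3, 10, 15, 7, 18), c(3, 10, 5, 15, 17, 3))
  I[idx] <- runif(6, 0.5, 1)   # isolated salt impulses, high amplitude
  for (s in c(2L, 3L, 5L)) {
    expect_true(all(morph_select(I, t = 0.15, s_size = s) == 0))
  }
})

test_that("recomposition is exact and linear in the contrast coefficient", {
  u <- rand_img(16, 16, seed = 28)
  Io <- lowpass_gaussian(u, 1.5)
  pr <- split_residual(residual(u, Io))
  expect_equal(compose_output(Io, pr$pos, pr$neg, 0), Io)
  expect_equal(compose_output(Io, pr$pos, pr$neg, 1), u)
  d1 <- compose_output(Io, pr$pos, pr$neg, 1) - Io
  d2 <- compose_output(Io, pr$pos, pr$neg, 2) - Io
  expect_equal(d2, 2 * d1)
})
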