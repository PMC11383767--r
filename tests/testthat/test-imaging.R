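# Bicubic kernel, resize, and the six augmentation primitives.

test_that("Keys kernel satisfies its defining identities", {
  expect_equal(cubic_kernel_weight(0), 1.0)
  expect_equal(cubic_kernel_weight(1), 0.0)
  expect_equal(cubic_kernel_weight(2), 0.0)
  expect_equal(cubic_kernel_weight(-1), 0.0)
  # direct evaluation: (a+2)|x|^3 - (a+3)|x|^2 + 1 at x = 0.5, a = -0.5
  expect_equal(cubic_kernel_weight(0.5), 1.5 * 0.125 - 2.5 * 0.25 + 1)
  expect_equal(cubic_kernel_weight(0.5), 0.5625)
  expect_equal(cubic_kernel_weight(3), 0)
})

test_that("kernel weights form a partition of unity at any phase", {
  set.seed(1)
  for (u in c(0, 0.25, 0.5, runif(20))) {
    w <- sum(cubic_kernel_weight(c(-1, 0, 1, 2) - u))
    expect_lt(abs(w - 1), 1e-9)
  }
  # holds for other sharpness coefficients of the family too
  for (a in c(-1, -0.75)) {
    u <- 0.37
    expect_lt(abs(sum(cubic_kernel_weight(c(-1, 0, 1, 2) - u, a)) - 1), 1e-9)
  }
})

test_that("bicubic resize preserves constants and reproduces linear ramps", {
  const <- image_array(array(128, c(30, 40, 3)))
  out <- resize_bicubic(const, 13, 17)
  expect_equal(dim(out), c(13L, 17L, 3L))
  expect_true(all(out == 128))

  # cubic convolution is exact on degree <= 1 signals: a bilinear ramp
  # v(r, c) = 2r + 3c resampled at the align-centers source coordinates
  h <- 32; w <- 32
  ramp <- array(0, c(h, w, 3))
  for (ch in 1:3) ramp[, , ch] <- outer(2 * seq_len(h), 3 * seq_len(w), "+")
  ramp <- image_array(ramp)
  out <- resize_bicubic(ramp, 16, 16)
  expect_equal(dim(out), c(16L, 16L, 3L))
  src_r <- (seq_len(16) - 0.5) * (h / 16) + 0.5
  src_c <- (seq_len(16) - 0.5) * (w / 16) + 0.5
  expected <- outer(2 * src_r, 3 * src_c, "+")
  # interior rows/cols (border taps are clamped, so exactness holds inside)
  expect_lte(max(abs(unclass(out)[2:15, 2:15, 1] - round(expected)[2:15, 2:15])), 1)
})

test_that("identity-scale resize reproduces the input within one level", {
  set.seed(2)
  img <- image_array(array(round(runif(24 * 24 * 3) * 255), c(24, 24, 3)))
  out <- resize_bicubic(img, 24, 24)
  expect_lte(max(abs(unclass(out) - unclass(img))), 1)
})

test_that("resize rejects invalid targets and accepts size-1 output", {
  img <- image_array(array(10, c(8, 8, 3)))
  expect_error(resize_bicubic(img, 0, 5), "target")
  expect_equal(dim(resize_bicubic(img, 1, 1)), c(1L, 1L, 3L))
})

test_that("rotation is a lossless pixel permutation with group structure", {
  set.seed(3)
  img <- image_array(array(round(runif(6 * 9 * 3) * 255), c(6, 9, 3)))
  r90 <- rotate_image(img, 90)
  expect_equal(dim(r90)[1:2], c(9L, 6L))
  expect_equal(sort(as.vector(unclass(r90))), sort(as.vector(unclass(img))))
  # rot90 twice == rot180; rot180 twice == identity
  expect_equal(unclass(rotate_image(r90, 90)), unclass(rotate_image(img, 180)))
  expect_equal(unclass(rotate_image(rotate_image(img, 180), 180)), unclass(img))
  expect_error(rotate_image(img, 45), "90 or 180")

  # 2x2 worked example: [[A,B],[C,D]] rotated clockwise -> [[C,A],[D,B]]
  tiny <- image_array(array(c(1, 3, 2, 4), c(2, 2, 3)))  # A=1 B=2 C=3 D=4
  rt <- unclass(rotate_image(tiny, 90))
  expect_equal(rt[1, 1, 1], 3)  # C
  expect_equal(rt[1, 2, 1], 1)  # A
  expect_equal(rt[2, 1, 1], 4)  # D
  expect_equal(rt[2, 2, 1], 2)  # B
})

test_that("mirroring flips columns and is an involution", {
  set.seed(4)
  img <- image_array(array(round(runif(5 * 7 * 3) * 255), c(5, 7, 3)))
  m <- mirror_image(img)
  for (j in 1:7) expect_equal(unclass(m)[, j, ], unclass(img)[, 7 + 1 - j, ])
  expect_equal(unclass(mirror_image(m)), unclass(img))
  sym <- image_array(array(rep(c(1, 2, 1), each = 4), c(4, 3, 3)))
  expect_equal(unclass(mirror_image(sym)), unclass(sym))
})

test_that("brightness scaling rounds and clamps per the stated rule", {
  img <- image_array(array(100, c(2, 2, 3)))
  expect_true(all(scale_brightness(img, 0.9) == 90))
  img2 <- image_array(array(200, c(2, 2, 3)))
  expect_true(all(scale_brightness(img2, 1.5) == 255))
  set.seed(5)
  img3 <- image_array(array(round(runif(12) * 255), c(2, 2, 3)))
  expect_equal(unclass(scale_brightness(img3, 1.0)), unclass(img3))
  expect_error(scale_brightness(img3, 0), "factor")
})

test_that("gaussian blur is a normalized separable convolution", {
  taps <- resswin:::gaussian_taps(1.0, 5L)
  expect_lt(abs(sum(taps) - 1), 1e-9)
  expect_error(resswin:::gaussian_taps(1.0, 4L), "odd")
  expect_error(gaussian_blur(image_array(array(1, c(4, 4, 3))), 1, 4L), "odd")

  const <- image_array(array(77, c(10, 10, 3)))
  expect_true(all(gaussian_blur(const, 1.5, 7L) == 77))

  # impulse response equals the outer product of the normalized 1-D taps
  n <- 11
  imp <- array(0, c(n, n, 3)); imp[6, 6, ] <- 255
  out <- gaussian_blur(image_array(imp), 1.0, 5L)
  expected <- round(255 * outer(taps, taps))
  got <- unclass(out)[4:8, 4:8, 1]
  expect_true(max(abs(got - expected)) <= 1)
})

test_that("the default augmentation set has exactly the six stated ops", {
  ops <- default_augment_ops()
  expect_named(ops, c("rot90", "rot180", "mirror", "dim", "brighten", "gauss"))
  expect_equal(ops$dim$factor, 0.9)
  expect_equal(ops$brighten$factor, 1.5)
  set.seed(6)
  img <- image_array(array(round(runif(8 * 8 * 3) * 255), c(8, 8, 3)))
  for (nm in names(ops)) {
    out <- apply_augment(img, ops[[nm]])
    d <- dim(out)
    if (nm == "rot90") expect_equal(d[1:2], dim(img)[2:1])
    else expect_equal(d[1:2], dim(img)[1:2])
    expect_equal(d[3], 3L)
    expect_true(min(out) >= 0 && max(out) <= 255)
    if (nm %in% c("rot90", "rot180", "mirror"))
      expect_equal(sort(as.vector(unclass(out))), sort(as.vector(unclass(img))))
  }
  expect_error(apply_augment(img, "nonesuch"), "unknown")
})

test_that("PNG round-trip preserves 8-bit pixel values", {
  set.seed(7)
  img <- image_array(array(round(runif(6 * 6 * 3) * 255), c(6, 6, 3)))
  f <- tempfile(fileext = ".png")
  write_image(img, f)
  expect_equal(unclass(read_image(f)), unclass(img))
  unlink(f)
})
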