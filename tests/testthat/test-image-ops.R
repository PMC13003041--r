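test_that("8-bit conversion rescales endpoints, rounds, and degrades gracefully", {
  s16 <- image_stack(matrix(c(0, 65535, 0, 65535), 2, 2), 0.1, 1,
                     bit_depth = 16)
  expect_equal(sort(unique(as.vector(to_uint8(s16)$voxels))), c(0, 255))

  const <- image_stack(matrix(700, 4, 4), 0.1, 1, bit_depth = 16)
  expect_true(all(to_uint8(const)$voxels == 0))

  s <- image_stack(matrix(c(0, 100, 200, 0), 2, 2), 0.1, 1, bit_depth = 16)
  expect_equal(sort(unique(as.vector(to_uint8(s)$voxels))), c(0, 128, 255))
})

test_that("contrast inversion is involutive and 8-bit only", {
  z <- image_stack(matrix(0, 3, 3), 0.1)
  expect_true(all(invert(z)$voxels == 255))
  s <- image_stack(matrix(c(10, 245, 3, 90), 2, 2), 0.1)
  expect_equal(invert(invert(s))$voxels, s$voxels)
  expect_equal(sort(unique(as.vector(invert(s)$voxels))),
               sort(255 - c(10, 245, 3, 90)))
  s16 <- image_stack(matrix(0, 2, 2), 0.1, bit_depth = 16)
  expect_error(invert(s16), "8-bit")
})

test_that("rolling-ball background matches brute-force ball opening", {
  set.seed(11)
  for (radius in c(3, 5)) {
    m <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
    s <- image_stack(m, 0.1)
    bg <- rolling_ball_background(s, radius)$background$voxels[, , 1]
    ref <- oracle_opening(m, radius)
    expect_true(max(abs(bg - ref)) <= 0.5)  # integer rounding of the output
  }
})

test_that("rolling-ball is anti-extensive, non-negative, and idempotent", {
  flat <- image_stack(matrix(37, 16, 16), 0.1)
  rb <- rolling_ball_background(flat, 4)
  expect_true(all(rb$background$voxels == 37))
  expect_true(all(rb$corrected$voxels == 0))

  spike <- matrix(0, 21, 21); spike[11, 11] <- 200
  rb <- rolling_ball_background(image_stack(spike, 0.1), 5)
  expect_equal(rb$corrected$voxels[11, 11, 1], 200)
  expect_true(all(rb$background$voxels[8:14, 8:14, 1] == 0))

  set.seed(12)
  m <- matrix(sample(0:255, 24 * 24, replace = TRUE), 24, 24)
  s <- image_stack(m, 0.1)
  rb <- rolling_ball_background(s, 3)
  expect_true(all(rb$corrected$voxels >= 0))
  expect_true(all(rb$background$voxels <= s$voxels))
  expect_true(all(rb$corrected$voxels + rb$background$voxels >=
                    s$voxels - 1))
  again <- rolling_ball_background(rb$background, 3)$background
  expect_true(max(abs(again$voxels - rb$background$voxels)) <= 1)

  expect_error(rolling_ball_background(s, 100), "larger")
})

test_that("constant subtraction clamps at zero", {
  s <- image_stack(matrix(c(5, 200, 10, 10), 2, 2), 0.1)
  expect_equal(subtract_constant(s, 0)$voxels, s$voxels)
  expect_equal(sort(unique(as.vector(subtract_constant(s, 50)$voxels))),
               c(0, 150))
  ten <- image_stack(matrix(10, 3, 3), 0.1)
  expect_true(all(subtract_constant(ten, 10)$voxels == 0))
})

test_that("median filter matches a per-pixel sort oracle and removes impulses", {
  const <- image_stack(matrix(42, 8, 8), 0.1)
  expect_equal(median_filter(const, 1)$voxels, const$voxels)

  imp <- matrix(0, 9, 9); imp[5, 5] <- 255
  expect_true(all(median_filter(image_stack(imp, 0.1), 1)$voxels == 0))

  set.seed(13)
  m <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  for (radius in c(1, 2)) {
    got <- median_filter(image_stack(m, 0.1), radius)$voxels[, , 1]
    expect_equal(got, oracle_median(m, radius))
  }
})

test_that("contrast enhancement stretches quantiles linearly", {
  full <- image_stack(matrix(c(0, 255, 100, 30), 2, 2), 0.1)
  expect_equal(enhance_contrast(full, 0)$voxels, full$voxels)

  two <- image_stack(matrix(c(50, 100), 4, 4), 0.1)
  expect_equal(sort(unique(as.vector(enhance_contrast(two, 0)$voxels))),
               c(0, 255))

  ramp <- image_stack(matrix(0:255, 16, 16), 0.1)
  got <- enhance_contrast(ramp, 0.1)$voxels
  q <- quantile(0:255, c(0.1, 0.9), names = FALSE)
  want <- pmin(pmax(floor((ramp$voxels - q[1]) / (q[2] - q[1]) * 255 + 0.5),
                    0), 255)
  expect_equal(got, want)

  const <- image_stack(matrix(7, 4, 4), 0.1)
  expect_warning(out <- enhance_contrast(const, 0), "degenerate")
  expect_equal(out$voxels, const$voxels)
})

test_that("gaussian blur preserves constants and reproduces the kernel", {
  const <- image_stack(matrix(100, 10, 10), 0.1)
  expect_true(max(abs(gaussian_blur(const, 2)$voxels - 100)) < 1e-9)

  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  got <- gaussian_blur(image_stack(imp, 0.1), 1.5)$voxels[, , 1]
  r <- ceiling(3 * 1.5)
  k <- dnorm(-r:r, sd = 1.5); k <- k / sum(k)
  # separable response: the centre row/column trace k scaled by k(0)
  expect_equal(got[8, (8 - r):(8 + r)], k * k[r + 1], tolerance = 1e-12)
  expect_equal(got[(8 - r):(8 + r), 8], k * k[r + 1], tolerance = 1e-12)
  expect_equal(got[(8 - r):(8 + r), (8 - r):(8 + r)], outer(k, k),
               tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)

  set.seed(14)
  m <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  wide <- gaussian_blur(image_stack(m, 0.1), 50)$voxels
  expect_true(max(abs(wide - mean(m))) < 30)
})

test_that("moments threshold matches the Prony re-derivation and is scale-invariant", {
  h <- rep(0, 256); h[51] <- 100; h[201] <- 100
  thr <- moments_threshold(h)
  expect_gte(thr, 50)
  expect_lt(thr, 200)

  h1 <- rep(0, 256); h1[8] <- 999
  expect_equal(moments_threshold(h1), 7)

  set.seed(15)
  for (i in 1:25) {
    h <- rep(0, 256)
    bins <- sample(0:255, 20)
    h[bins + 1] <- sample(1:500, 20, replace = TRUE)
    expect_equal(moments_threshold(h), oracle_moments_threshold(h),
                 info = paste("histogram", i))
    expect_equal(moments_threshold(h * 7), moments_threshold(h))
  }
})

test_that("connected components agree with a flood-fill oracle", {
  empty <- binarize(image_stack(matrix(0, 6, 6), 0.1), 0)
  empty$voxels[] <- FALSE
  expect_equal(nrow(connected_components(empty)$particles), 0)

  vox <- array(FALSE, c(4, 4, 3))
  vox[2, 2, 1] <- TRUE; vox[3, 3, 2] <- TRUE  # diagonal in 3-D
  b <- structure(list(voxels = vox, pixel_size = 0.1, z_step = 1),
                 class = "binary_stack")
  cc26 <- connected_components(b, connectivity = 26)
  expect_equal(nrow(cc26$particles), 1)
  expect_equal(cc26$particles$n_voxels, 2)
  cc6 <- connected_components(b, connectivity = 6)
  expect_equal(nrow(cc6$particles), 2)

  set.seed(16)
  for (i in 1:5) {
    vox <- array(runif(16^3) < 0.25, c(16, 16, 16))
    b <- structure(list(voxels = vox, pixel_size = 0.1, z_step = 1),
                   class = "binary_stack")
    cc <- connected_components(b)
    ref <- oracle_flood_fill(vox)
    expect_equal(nrow(cc$particles), max(ref))
    expect_equal(sum(cc$particles$n_voxels), sum(vox))
  }
})

test_that("particle geometry is physically calibrated", {
  vox <- array(FALSE, c(8, 8, 4))
  vox[3:5, 3:6, 2] <- TRUE   # 12 px slice
  vox[4, 4, 3] <- TRUE
  b <- structure(list(voxels = vox, pixel_size = 0.25, z_step = 2),
                 class = "binary_stack")
  p <- connected_components(b)$particles
  expect_equal(nrow(p), 1)
  expect_equal(p$n_voxels, 13)
  expect_equal(p$volume_um3, 13 * 0.25^2 * 2)
  expect_equal(p$max_slice_area_um2, 12 * 0.25^2)
})

test_that("raising the binarisation threshold never increases foreground", {
  set.seed(17)
  s <- image_stack(matrix(sample(0:255, 400, replace = TRUE), 20, 20), 0.1)
  counts <- vapply(c(0, 64, 128, 192, 255),
                   function(t) sum(binarize(s, t)$voxels), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
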