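test_that("gamma correction matches its closed form", {
  f <- matrix(as.numeric(0:63), 8, 8)
  expect_identical(gamma_correct(f, 1), f)
  expect_equal(gamma_correct(matrix(0, 8, 8), 0.3), matrix(0, 8, 8))
  # 255 * (64/255)^0.5 = 127.75 -> 128
  expect_equal(gamma_correct(matrix(64, 8, 8), 0.5)[1, 1], 128)
  expect_error(gamma_correct(f, 0), "positive")
})

test_that("brightness adjustment is elementwise scaling", {
  f <- matrix(100, 8, 8)
  expect_identical(adjust_brightness(f, 1), f)
  expect_true(all(adjust_brightness(f, 0) == 0))
  expect_true(all(adjust_brightness(f, 1.2) == 120))
  expect_true(all(adjust_brightness(matrix(255, 4, 4), 2) == 255)) # clipped
})

test_that("sharpness blends against the 3x3 smoothing kernel", {
  f <- matrix(77, 9, 9)
  expect_identical(adjust_sharpness(f, 0), f)    # constants are fixed points
  expect_identical(adjust_sharpness(f, 1), f)
  expect_identical(adjust_sharpness(f, 5), f)

  delta <- matrix(0, 9, 9); delta[5, 5] <- 130
  blurred <- adjust_sharpness(delta, 0)
  # oracle: direct convolution with the [1 1 1; 1 5 1; 1 1 1]/13 kernel
  k <- matrix(c(1, 1, 1, 1, 5, 1, 1, 1, 1), 3, 3) / 13
  expect_equal(blurred[5, 5], round(130 * k[2, 2]))
  expect_equal(blurred[4, 4], round(130 * k[1, 1]))
  expect_equal(blurred[4, 5], round(130 * k[1, 2]))
  expect_equal(blurred[6, 6], round(130 * k[3, 3]))
  expect_equal(sum(blurred != 0), 9)
  rnd <- tiny_frames(T = 1, H = 9, W = 9, seed = 4)[1, , ]
  expect_identical(adjust_sharpness(rnd, 1), rnd) # blend midpoint = identity
})

test_that("noise operators honour their parameters", {
  f <- matrix(128, 16, 16)
  set.seed(1)
  expect_identical(add_noise(f, "salt_pepper", theta = 0), f)
  expect_identical(add_noise(f, "gaussian", sigma = 0), f)
  expect_identical(add_noise(f, "speckle", strength = 0), f)
  expect_error(add_noise(f, "shot"), "unknown noise kind")

  # binomial expectation: 2 * theta * Npix corrupted pixels on average
  set.seed(2)
  npix <- 224 * 224; theta <- 0.005; trials <- 40
  counts <- replicate(trials, {
    g <- add_noise(matrix(128, 224, 224), "salt_pepper", theta = theta)
    sum(g != 128)
  })
  expected <- 2 * theta * npix
  se <- sqrt(npix * 2 * theta * (1 - 2 * theta) / trials)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("affine transform agrees with a brute-force remap oracle", {
  f <- tiny_frames(T = 1, H = 9, W = 9, seed = 5)[1, , ]
  expect_identical(affine_transform(f, 0, 0, 0, 1), f)

  cst <- matrix(60, 9, 9)
  out <- affine_transform(cst, 30, 0.05, -0.05, 1.1)
  expect_true(all(out %in% c(0, 60)))

  # 90 degrees about the center: output(r, c) = input(c, H+1-r) under the
  # package's inverse-map convention; oracle loops over every pixel
  g <- affine_transform(f, 90, 0, 0, 1)
  oracle <- matrix(0, 9, 9)
  a <- pi / 2; cy <- 5; cx <- 5
  for (r in 1:9) for (c in 1:9) {
    xs <- cos(a) * (c - cx) + sin(a) * (r - cy) + cx
    ys <- -sin(a) * (c - cx) + cos(a) * (r - cy) + cy
    xs <- round(xs); ys <- round(ys)
    if (xs >= 1 && xs <= 9 && ys >= 1 && ys <= 9) oracle[r, c] <- f[ys, xs]
  }
  expect_identical(g, oracle)
})

test_that("augment_clip with identity parameters is the exact identity", {
  ident <- augment_config(p_transform = 1, p_sample = 1,
                          blur_range = c(1, 1), sharpen_range = c(1, 1),
                          brightness_range = c(1, 1), gamma_range = c(1, 1),
                          sp_threshold = 0, gaussian_sigma_range = c(0, 0),
                          speckle_range = c(0, 0), rotation_range = c(0, 0),
                          translation_max = 0, scale_range = c(1, 1))
  clip <- tiny_frames(T = 4, H = 12, W = 12, seed = 6)
  set.seed(3)
  expect_identical(augment_clip(clip, ident), clip)

  off <- augment_config(p_sample = 0)
  set.seed(4)
  expect_identical(augment_clip(clip, off), clip)
})

test_that("augmentation is deterministic given the seed", {
  clip <- tiny_frames(T = 3, H = 16, W = 16, seed = 7)
  cfg <- augment_config()
  set.seed(123); a <- augment_clip(clip, cfg)
  set.seed(123); b <- augment_clip(clip, cfg)
  expect_identical(a, b)
})

test_that("transform parameters are shared across a sequence", {
  # all frames identical in, all frames identical out, whatever fired
  base <- tiny_frames(T = 1, H = 16, W = 16, seed = 8)[1, , ]
  clip <- array(rep(base, each = 5), c(5, 16, 16))
  for (s in 1:10) {
    set.seed(s)
    out <- augment_clip(clip, augment_config(p_sample = 1))
    for (t in 2:5) expect_identical(out[t, , ], out[1, , ])
  }
})

test_that("outputs remain valid 8-bit frames of unchanged shape", {
  clip <- tiny_frames(T = 3, H = 12, W = 12, seed = 9)
  for (s in 1:12) {
    set.seed(100 + s)
    out <- augment_clip(clip, augment_config(p_sample = 1))
    expect_identical(dim(out), dim(clip))
    expect_true(all(out >= 0 & out <= 255))
    expect_true(all(out == round(out)))
  }
})
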