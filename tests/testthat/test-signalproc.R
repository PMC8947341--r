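# Noise estimation, thresholding, ROI masking and the two normalizations.

test_that("corner_background pools the four corner patches", {
  img <- magnitude_image(matrix(3.7, 64, 64), c(1, 1))
  ns <- corner_background(img, 0.125)
  expect_equal(ns$mean_bg, 3.7)
  expect_equal(ns$std_bg, 0)
  expect_equal(ns$n_pixels, 4L * 8L * 8L)
})

test_that("fraction 1/8 on a 256 grid gives four 32 x 32 patches", {
  img <- rand_image(256, 256, seed = 1)
  ns <- corner_background(img, 1 / 8)
  expect_equal(ns$n_pixels, 4096L)
  # check against a direct computation over explicitly indexed corners
  px <- img$pixels
  pool <- c(px[1:32, 1:32], px[1:32, 225:256],
            px[225:256, 1:32], px[225:256, 225:256])
  expect_equal(ns$mean_bg, mean(pool))
  expect_equal(ns$std_bg, sd(pool))
})

test_that("corner patches cannot exceed half the image", {
  img <- rand_image(16, 16)
  expect_error(corner_background(img, 0.6), "0.5")
  expect_no_error(corner_background(img, 0.5))
})

test_that("corner mean recovers the Rayleigh mean on pure noise", {
  # magnitude of iid complex Gaussian (sigma = 1) has mean sqrt(pi/2)
  set.seed(123)
  means <- replicate(10, {
    img <- magnitude_image(
      matrix(sqrt(rnorm(64^2)^2 + rnorm(64^2)^2), 64, 64), c(1, 1))
    corner_background(img, 0.25)$mean_bg
  })
  rayleigh_mean <- sqrt(pi / 2)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - rayleigh_mean), 3 * se + 1e-12)
})

test_that("threshold keeps exactly the pixels at >= multiplier x mean", {
  # probe ladder: pixels at 1..10 times the corner mean
  base <- matrix(1, 20, 20)
  base[10, 5 + (1:10)] <- 1:10
  img <- magnitude_image(base, c(1, 1))
  ns <- corner_background(img, 0.25)  # corners are constant 1
  expect_equal(ns$mean_bg, 1)
  den <- threshold_denoise(img, ns, 5)
  survived <- den$pixels[10, 5 + (1:10)]
  expect_equal(survived, c(0, 0, 0, 0, 5, 6, 7, 8, 9, 10))
  expect_true("denoised" %in% den$provenance)
})

test_that("threshold multiplier 0 leaves a nonnegative image unchanged", {
  img <- rand_image(12, 12, seed = 3)
  ns <- corner_background(img, 0.25)
  expect_equal(threshold_denoise(img, ns, 0)$pixels, img$pixels)
  expect_error(threshold_denoise(img, ns, -1), "nonnegative")
})

test_that("thresholding is idempotent and never increases a pixel", {
  img <- rand_image(32, 32, seed = 4)
  ns <- corner_background(img, 0.125)
  once <- threshold_denoise(img, ns, 5)
  twice <- threshold_denoise(once, ns, 5)
  expect_identical(once$pixels, twice$pixels)
  expect_true(all(once$pixels <= img$pixels))
  changed <- once$pixels != img$pixels
  expect_true(all(once$pixels[changed] == 0))
})

test_that("quad mask agrees with the brute-force point-in-polygon oracle", {
  img <- rand_image(10, 10, seed = 5, spacing = c(1, 1))
  quads <- list(
    quad_roi(c(2, 2, 8, 2, 8, 8, 2, 8)),          # axis-aligned
    quad_roi(c(5, 0.5, 9.5, 5, 5, 9.5, 0.5, 5)),  # diamond
    quad_roi(c(1, 1, 9, 2, 7, 9, 2, 6)))          # irregular
  for (q in quads) {
    masked <- apply_roi_mask(img, q)
    vx <- q$vertices[, 1]; vy <- q$vertices[, 2]
    for (i in 1:10) for (j in 1:10) {
      inside <- oracle_point_in_poly(j - 0.5, i - 0.5, vx, vy)
      if (inside) expect_identical(masked$pixels[i, j], img$pixels[i, j])
      else expect_identical(masked$pixels[i, j], 0)
    }
  }
})

test_that("a quad covering the full extent leaves the image unchanged", {
  img <- rand_image(8, 8, seed = 6, spacing = c(1, 1))
  q <- quad_roi(c(0, 0, 8, 0, 8, 8, 0, 8))
  masked <- apply_roi_mask(img, q)
  expect_equal(masked$pixels, img$pixels)
  expect_true("masked" %in% masked$provenance)
})

test_that("degenerate and self-intersecting quads are rejected", {
  expect_error(quad_roi(c(1, 1, 1, 1, 1, 1, 1, 1)), "zero area")
  expect_error(quad_roi(c(0, 0, 5, 0, 5, 5, 2.5, -3)), "self-intersecting")
})

test_that("phantom normalization divides by the reference and cancels drift", {
  img <- rand_image(16, 16, seed = 7)
  expect_equal(phantom_normalize(img, 1)$pixels, img$pixels)
  expect_equal(max(phantom_normalize(
    magnitude_image(matrix(8, 2, 2), c(1, 1)), 2)$pixels), 4)
  # common drift factor cancels: the reason the phantom is scanned at all
  for (drift in c(0.25, 1.7, 40)) {
    drifted <- img; drifted$pixels <- drifted$pixels * drift
    expect_equal(phantom_normalize(drifted, 3 * drift)$pixels,
                 phantom_normalize(img, 3)$pixels, tolerance = 1e-12)
  }
  expect_error(phantom_normalize(img, 0), "positive")
  expect_error(phantom_normalize(img, -2), "positive")
  expect_true("phantom_normalized" %in%
                phantom_normalize(img, 2)$provenance)
})

test_that("set_normalize scales by the single universal peak", {
  a <- magnitude_image(matrix(c(1, 2, 0, 1), 2, 2), c(1, 1))
  b <- magnitude_image(matrix(c(0, 4, 2, 1), 2, 2), c(1, 1))
  ns <- set_normalize(list(a, b))
  expect_equal(ns$universal_peak, 4)
  expect_equal(ns$per_study_peaks, c(2, 4))
  expect_equal(max(ns$images[[1]]$pixels), 0.5)
  expect_equal(max(ns$images[[2]]$pixels), 1)
  single <- set_normalize(list(a))
  expect_equal(max(single$images[[1]]$pixels), 1)
  expect_error(set_normalize(list(magnitude_image(matrix(0, 2, 2), 1))),
               "zero")
})

test_that("set normalization preserves every between-study mean ratio", {
  set.seed(8)
  imgs <- lapply(1:12, function(i)
    magnitude_image(matrix(runif(64, 0, i), 8, 8), c(1, 1)))
  before <- vapply(imgs, function(im) mean(im$pixels), numeric(1))
  ns <- set_normalize(imgs)
  after <- vapply(ns$images, function(im) mean(im$pixels), numeric(1))
  for (i in 1:11) for (j in (i + 1):12)
    expect_equal(after[i] / after[j], before[i] / before[j],
                 tolerance = 1e-12)
  expect_equal(max(vapply(ns$images, function(im) max(im$pixels),
                          numeric(1))), 1)
})

test_that("full per-study chain lands in [0, 1] and localizes the focus", {
  # mask -> threshold -> phantom-normalize -> set-normalize; the only
  # supra-threshold signal is the planted focus, so the argmax must fall
  # inside it even with the brighter beacon outside the quad
  p <- synth_params(seed = 21)
  sk <- make_silicon_kspace(p, tumor_amplitude_scale = 1, seed = 33)
  rec <- reconstruct(zero_fill(sk$kspace, 256, 256))
  ns <- corner_background(rec, 0.125)
  quad <- quad_roi(c(68, 32, 188, 32, 188, 232, 68, 232))
  chain <- phantom_normalize(
    threshold_denoise(apply_roi_mask(rec, quad), ns, 5), 50)
  out <- set_normalize(list(chain))$images[[1]]
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
  w <- which(out$pixels == max(out$pixels), arr.ind = TRUE)[1, ]
  # nearest planted focus within its radius (tumor 1: 28,44 mm, r 4 mm)
  pos_mm <- c(w[2], w[1]) * 0.25
  d1 <- sqrt(sum((pos_mm - c(28, 44))^2))
  d2 <- sqrt(sum((pos_mm - c(37, 40))^2))
  expect_lt(min(d1, d2), 4)
})
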