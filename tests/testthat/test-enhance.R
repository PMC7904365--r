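test_that("gaussian kernel is normalized, symmetric and peaked at center", {
  for (sig in c(0.7, 1, 2.5)) {
    k <- gaussian_kernel(sig, 5L)
    expect_lt(abs(sum(k) - 1), 1e-12)
    expect_identical(k, t(k))
    expect_identical(k, k[5:1, ])
    expect_equal(which.max(k), 13L)  # center of a 5x5
  }
  # center/corner ratio before normalization: exp(0) / exp(-(2^2+2^2)/2) = e^4
  k <- gaussian_kernel(1, 5L)
  expect_equal(k[3, 3] / k[1, 1], exp(4))
  expect_error(gaussian_kernel(1, 4L), class = "octedema_spec_error")
  expect_error(gaussian_kernel(0, 5L), class = "octedema_spec_error")
})

test_that("gf_smooth preserves constants, reproduces the impulse response, and smooths", {
  expect_equal(gf_smooth(matrix(0.4, 12, 12)), matrix(0.4, 12, 12))
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  out <- gf_smooth(imp, 1, 5L)
  expect_equal(out[6:10, 6:10], gaussian_kernel(1, 5L))
  # convexity: output range within input range
  x <- matrix(runif(400), 20, 20)
  sm <- gf_smooth(x)
  expect_gte(min(sm), min(x))
  expect_lte(max(sm), max(x))
  # variance reduction inside the speckled band
  p <- generate_phantom(small_spec(seed = 1))
  band <- p$retina_mask & !p$edema_mask
  expect_lt(var(gf_smooth(p$image)[band]), var(p$image[band]))
})

test_that("structure transfer satisfies its analytic limits", {
  set.seed(42)
  x <- matrix(runif(12 * 10), 12, 10)
  # guidance = the image's own forward differences => identity
  gd <- list(vh = cbind(x[, -1] - x[, -10], 0), vv = rbind(x[-1, ] - x[-12, ], 0))
  expect_lt(max(abs(structure_transfer(x, gd, 0.1) - x)), 1e-6)
  # lambda -> Inf returns the input regardless of guidance
  junk <- list(vh = matrix(runif(120), 12, 10), vv = matrix(runif(120), 12, 10))
  expect_lt(max(abs(structure_transfer(x, junk, 1e6) - x)), 1e-3)
  expect_error(structure_transfer(x, list(vh = x[1:3, 1:3], vv = x), 1),
               class = "octedema_shape_error")
  expect_error(structure_transfer(x, junk, 0), class = "octedema_spec_error")
})

test_that("structure transfer matches a dense direct solve", {
  set.seed(7)
  for (rep in 1:5) {
    h <- sample(4:16, 1); w <- sample(4:16, 1)
    img <- matrix(runif(h * w), h, w)
    other <- matrix(runif(h * w), h, w)
    gd <- guidance_field(other, 1.5)
    lam <- sample(c(0.05, 0.1, 1), 1)
    got <- structure_transfer(img, gd, lam)
    want <- oracle_structure_transfer(img, gd$vh, gd$vv, lam)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("guidance field reflects large-scale geometry", {
  expect_equal(guidance_field(matrix(0.3, 10, 10))$vh, matrix(0, 10, 10))
  expect_equal(guidance_field(matrix(0.3, 10, 10))$vv, matrix(0, 10, 10))
  # vertical step edge: horizontal component concentrated at the step
  step <- cbind(matrix(0, 24, 12), matrix(1, 24, 12))
  gd <- guidance_field(step, 1)
  expect_gt(max(abs(gd$vh)), 0.1)
  expect_lt(max(abs(gd$vv)), 1e-8)
  expect_true(all(abs(gd$vh[, c(1:7, 17:24)]) < 1e-6))
})

test_that("structure transfer re-sharpens smoothed edges", {
  step <- cbind(matrix(0.1, 32, 16), matrix(0.9, 32, 16))
  sm <- gf_smooth(step, 1.5, 9L)
  out <- structure_transfer(sm, guidance_field(step, 0.5), 0.05)
  edge_grad <- function(x) max(abs(x[, 17] - x[, 16]))
  expect_gt(edge_grad(out), edge_grad(sm))
})

test_that("retinex surround kernel and constant-image null are exact", {
  for (cc in c(3, 15, 40)) {
    k <- octedema:::surround_kernel(cc)
    expect_lt(abs(sum(k) - 1), 1e-12)
  }
  r <- retinex_ssr(matrix(0.7, 20, 20), c = 5, rescale = FALSE)
  expect_equal(r, matrix(0, 20, 20))
  expect_error(retinex_ssr(matrix(0.5, 8, 8), c = -1), class = "octedema_spec_error")
})

test_that("retinex log-ratio is signed across a two-level boundary", {
  img <- rbind(matrix(0.2, 8, 16), matrix(0.8, 8, 16))
  r <- retinex_ssr(img, c = 4, rescale = FALSE)
  expect_gt(r[9, 8], 0)   # bright side of the edge
  expect_lt(r[8, 8], 0)   # dark side of the edge
})

test_that("the full enhancement recovers clean structure and is deterministic", {
  # cavity-free piecewise-constant band: thresholding the enhanced image
  # must recover the band geometry almost exactly
  p <- generate_phantom(phantom_spec(edema = list(), speckle_shape = 1e9,
                                     background_noise_sd = 0, seed = 3))
  enh <- enhance(p$clean)
  th <- EBImage::otsu(enh, range = c(0, 1))
  expect_gte(dice_of(enh > th, p$retina_mask), 0.98)
  expect_true(all(enh >= 0 & enh <= 1))
  sp <- generate_phantom(small_spec(seed = 3))
  expect_identical(enhance(sp$image), enhance(sp$image))
})
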